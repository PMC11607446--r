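test_that("delta to atom percent matches the two-isotope closed form", {
  r2h <- 0.00015576
  # independent evaluation of R/(1+R) at the VSMOW definition
  expect_equal(delta_to_atom_percent(0, r2h),
               100 * r2h / (1 + r2h), tolerance = 1e-12)
  # delta = 1000 permil doubles the isotope ratio
  r2 <- 2 * r2h
  expect_equal(delta_to_atom_percent(1000, r2h),
               100 * r2 / (1 + r2), tolerance = 1e-12)
  # printed-precision anchors
  expect_equal(delta_to_atom_percent(0, r2h), 0.015574, tolerance = 1e-4)
  expect_equal(delta_to_atom_percent(1000, r2h), 0.031142, tolerance = 1e-4)
})

test_that("delta/atom-percent conversion round-trips and is monotone bounded", {
  r18o <- 0.0020052
  set.seed(11)
  d <- sort(stats::runif(200, -900, 5e4))
  at <- delta_to_atom_percent(d, r18o)
  expect_true(all(at > 0 & at < 100))
  expect_true(all(diff(at) > 0))
  expect_equal(atom_percent_to_delta(at, r18o), d, tolerance = 1e-10)
  expect_error(delta_to_atom_percent(-1000, r18o), class = "vs_domain_error")
  expect_error(atom_percent_to_delta(0, r18o), class = "vs_domain_error")
})

test_that("calibration line recovers slope and intercept", {
  exact <- tibble::tibble(known_delta = c(-183, 0, 384),
                          measured_delta = c(-183, 0, 384))
  cal <- fit_calibration(exact)
  expect_equal(cal$slope, 1, tolerance = 1e-12)
  expect_equal(cal$intercept, 0, tolerance = 1e-12)

  # two-point line solved by hand: slope 567/567 = 1, intercept +10
  two <- tibble::tibble(known_delta = c(-183, 384),
                        measured_delta = c(-193, 374))
  cal2 <- fit_calibration(two)
  expect_equal(cal2$slope, 1, tolerance = 1e-12)
  expect_equal(cal2$intercept, 10, tolerance = 1e-12)
  expect_equal(apply_calibration(-193, cal2), -183, tolerance = 1e-12)

  expect_error(fit_calibration(tibble::tibble(known_delta = 100,
                                              measured_delta = 90)),
               class = "vs_degenerate_fit_error")
  expect_error(
    fit_calibration(tibble::tibble(known_delta = c(-183, 384),
                                   measured_delta = c(50, 50))),
    class = "vs_degenerate_fit_error")
})

test_that("drift correction is linear in run position", {
  cal <- structure(list(slope = 1, intercept = 0, drift_per_index = 0.5,
                        residual_sd = 0, n = 4), class = "vs_calibration")
  expect_equal(apply_calibration(-100, cal, run_index = 10), -105)

  # standards drifting +0.3 permil per injection are recovered
  std <- tidyr::expand_grid(known_delta = c(-183, 384),
                            run_index = c(0, 10, 20, 30)) |>
    dplyr::mutate(measured_delta = known_delta + 0.3 * run_index)
  cal2 <- fit_calibration(std)
  corrected <- apply_calibration(std$measured_delta, cal2, std$run_index)
  expect_equal(corrected, std$known_delta, tolerance = 1e-8)
})

test_that("calibration applied to the standards reproduces known values within residual sd", {
  set.seed(21)
  std <- tibble::tibble(
    known_delta = rep(c(-183, 100, 384), each = 4),
    run_index = rep(1:4, times = 3)
  ) |>
    dplyr::mutate(measured_delta = (known_delta - 8) / 1.02 +
                    stats::rnorm(dplyr::n(), 0, 4))
  cal <- fit_calibration(std)
  back <- apply_calibration(std$measured_delta, cal, std$run_index)
  expect_true(mean(abs(back - std$known_delta)) <= 2 * max(cal$residual_sd, 4))
  expect_named(generics::tidy(cal), c("term", "estimate"))
  expect_equal(generics::glance(cal)$n, nrow(std))
})

test_that("fatty-acid carbon is quantified against the internal standard", {
  meta <- tibble::tibble(sample_id = c("s1", "s2"),
                         soil_dry_mass = c(1, 0.8))
  areas <- tibble::tribble(
    ~sample_id, ~marker,  ~peak_area,
    "s1",       "16:0",   500,
    "s1",       "19:0",   500,
    "s2",       "16:0",   250,
    "s2",       "18:0",   0,
    "s2",       "19:0",   500
  )
  out <- quantify_fa_carbon(areas, is_carbon = 1000, meta = meta)
  expect_equal(out$fa_c[out$sample_id == "s1"], 1000)          # area == IS, 1 g
  expect_equal(out$fa_c[out$sample_id == "s2" & out$marker == "16:0"],
               250 / 500 * 1000 / 0.8)                          # 625 ng C/g
  expect_equal(out$fa_c[out$sample_id == "s2" & out$marker == "18:0"], 0)
  expect_false("19:0" %in% out$marker)  # IS never enters downstream sums

  expect_error(
    quantify_fa_carbon(dplyr::filter(areas, marker != "19:0"),
                       1000, meta),
    class = "vs_quantification_error")
})
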