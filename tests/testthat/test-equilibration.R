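make_series <- function(at_start, at_end, b, times = c(0, 3, 6, 16, 48)) {
  tibble::tibble(time_h = times,
                 atom_percent = at_end + (at_start - at_end) * exp(-b * times))
}

test_that("soil enrichment follows two-pool mass balance of source-label loss", {
  src <- tibble::tibble(time_h = c(0, 3, 48), atom_percent = c(20, 15, 10))

  # unchanged source -> soil stays at natural abundance
  flat <- dplyr::mutate(src, atom_percent = 20)
  out0 <- source_loss_to_soil_atpct(flat, 0.5, 0.5, 0.0155)
  expect_equal(out0$atom_percent, rep(0.0155, 3))

  # equal masses, source drops 20 -> 10: soil gains the full 10 at%
  out <- source_loss_to_soil_atpct(src, 0.5, 0.5, 0.0155)
  expect_equal(out$atom_percent[3], 10.0155, tolerance = 1e-12)

  # heavy-isotope amount conserved at every time point
  total <- 0.5 * src$atom_percent + 0.5 * out$atom_percent
  expect_equal(total, rep(total[1], 3), tolerance = 1e-12)

  expect_error(source_loss_to_soil_atpct(src, -1, 0.5, 0.0155),
               class = "vs_domain_error")
  rising <- dplyr::mutate(src, atom_percent = c(10, 15, 40))
  expect_error(source_loss_to_soil_atpct(rising, 2, 0.1, 0.0155),
               class = "vs_mass_balance_error")
})

test_that("exponential fit recovers noise-free parameters to 1e-6 relative", {
  s <- make_series(0.0155, 16.1, 0.12)
  fit <- fit_equilibration(s, window = 48)
  expect_equal(fit$at_start, 0.0155, tolerance = 1e-6)
  expect_equal(fit$at_end, 16.1, tolerance = 1e-6)
  expect_equal(fit$b, 0.12, tolerance = 1e-6)
  expect_false(fit$degenerate)
  # fitted curve passes through the anchor observations
  expect_equal(predict(fit, c(0, 48)), s$atom_percent[c(1, 5)],
               tolerance = 1e-6)
})

test_that("flat series yields a flagged degenerate fit, short series errors", {
  flat <- tibble::tibble(time_h = c(0, 6, 48), atom_percent = rep(5, 3))
  fit <- fit_equilibration(flat)
  expect_true(fit$degenerate)
  expect_equal(fit$at_start, fit$at_end)
  expect_equal(fit$average_atpct, 5)

  expect_error(fit_equilibration(flat[1:2, ]), class = "vs_data_error")
  expect_error(
    fit_equilibration(tibble::tibble(time_h = c(3, 6, 16),
                                     atom_percent = c(1, 2, 3))),
    class = "vs_data_error")
})

test_that("noisy series are recovered within 5% relative for 95% of seeds", {
  n_rep <- 500
  truth <- c(at_start = 0.0155, at_end = 16.1, b = 0.12)
  ok <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    set.seed(i)
    s <- make_series(truth[1], truth[2], truth[3])
    s$atom_percent <- s$atom_percent + stats::rnorm(nrow(s), 0, 0.1)
    fit <- tryCatch(fit_equilibration(s), error = function(e) NULL)
    ok[i] <- !is.null(fit) &&
      abs(fit$at_end / truth["at_end"] - 1) < 0.05 &&
      abs(fit$b / truth["b"] - 1) < 0.05
  }
  expect_gte(mean(ok), 0.95)
})

test_that("window-average enrichment matches the closed form and its limits", {
  # hand evaluation: 16.1 + (0.0155 - 16.1) * (1 - exp(-4.8)) / 4.8
  fit <- list(at_start = 0.0155, at_end = 16.1, b = 0.1, window = 48,
              degenerate = FALSE)
  hand <- 16.1 + (0.0155 - 16.1) * (1 - exp(-0.1 * 48)) / (0.1 * 48)
  expect_equal(average_enrichment(fit), hand, tolerance = 1e-12)
  expect_equal(average_enrichment(fit), 12.78, tolerance = 1e-3)

  # b -> Inf: average collapses to the plateau
  fit$b <- 1e6
  expect_equal(average_enrichment(fit), 16.1, tolerance = 1e-3)
  # b -> 0: average tends to the start value (deviation ~ (end-start)*bW/2)
  fit$b <- 1e-9
  expect_lt(abs(average_enrichment(fit) - 0.0155), 1e-6)
})

test_that("closed-form average agrees with numeric quadrature on random draws", {
  set.seed(99)
  n <- 1000
  at_start <- stats::runif(n, 0, 1)
  at_end <- stats::runif(n, 5, 30)
  b <- 10^stats::runif(n, -3, 1)
  w <- 48
  for (i in seq_len(n)) {
    closed <- average_enrichment(list(at_start = at_start[i],
                                      at_end = at_end[i], b = b[i],
                                      window = w, degenerate = FALSE))
    quad <- pracma::integral(
      function(t) at_end[i] + (at_start[i] - at_end[i]) * exp(-b[i] * t),
      0, w) / w
    expect_equal(closed, quad, tolerance = 1e-9)
  }
})

test_that("average enrichment is monotone in the plateau and lies between endpoints", {
  ends <- seq(5, 30, by = 0.5)
  avgs <- vapply(ends, function(e) {
    average_enrichment(list(at_start = 0.0155, at_end = e, b = 0.1,
                            window = 48, degenerate = FALSE))
  }, numeric(1))
  expect_true(all(diff(avgs) > 0))
  expect_true(all(avgs > 0.0155 & avgs < ends))
})

test_that("treatment-level averages map recovery to the non-drought climate", {
  truth <- truth_noise_free()
  water <- simulate_water_series(truth, seed = 3)
  tbl <- treatment_water_enrichment(water, window = 48)
  expect_setequal(unique(tbl$phase), c("drought", "recovery"))
  amb <- function(ph) tbl$soil_water_atpct[tbl$tracer == "2h" &
                                             tbl$phase == ph &
                                             tbl$treatment == "ambient"]
  drt_rec <- tbl$soil_water_atpct[tbl$tracer == "2h" &
                                    tbl$phase == "recovery" &
                                    tbl$treatment == "drought"]
  expect_equal(drt_rec, amb("drought"))
  expect_equal(drt_rec, amb("recovery"))
})
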