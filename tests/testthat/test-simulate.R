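test_that("the same seed reproduces the dataset exactly", {
  t1 <- vs_truth()
  d1 <- vs_simulate_dataset(t1, seed = 17)
  d2 <- vs_simulate_dataset(t1, seed = 17)
  for (nm in c("meta", "fame", "water", "dna", "headspace", "expected")) {
    expect_identical(d1[[nm]], d2[[nm]])
  }
  d3 <- vs_simulate_dataset(t1, seed = 18)
  expect_false(identical(d1$fame, d3$fame))
  expect_error(vs_simulate_dataset(t1), class = "vs_truth_error")
})

test_that("water series conserve label between pools and invert the fitter", {
  truth <- truth_noise_free()
  w <- simulate_water_series(truth, seed = 9)
  wide <- tidyr::pivot_wider(w, names_from = "pool",
                             values_from = "atom_percent")
  total <- truth$source_water_mass * wide$source +
    truth$soil_water_mass * wide$soil
  per_series <- split(total, paste(wide$tracer, wide$treatment,
                                   wide$replicate))
  for (tot in per_series) {
    expect_equal(tot, rep(tot[1], length(tot)), tolerance = 1e-12)
  }

  # fitting a simulated soil series recovers the generating parameters
  one <- dplyr::filter(w, .data$tracer == "2h", .data$treatment == "ambient",
                       .data$replicate == 1, .data$pool == "soil")
  fit <- fit_equilibration(one)
  pars <- dplyr::filter(truth$water, .data$tracer == "2h",
                        .data$treatment == "ambient")
  expect_equal(fit$at_start, pars$at_start, tolerance = 1e-6)
  expect_equal(fit$at_end, pars$at_end, tolerance = 1e-6)
  expect_equal(fit$b, pars$b, tolerance = 1e-6)

  # a (near-)zero rate constant gives a flat series
  slow <- truth_noise_free(
    water = dplyr::mutate(truth$water, b = 1e-9))
  wflat <- simulate_water_series(slow, seed = 9) |>
    dplyr::filter(.data$pool == "soil", .data$tracer == "2h",
                  .data$treatment == "ambient", .data$replicate == 1)
  expect_lt(diff(range(wflat$atom_percent)), 1e-6)
})

test_that("zero growth everywhere leaves biomarkers at natural abundance", {
  truth <- truth_noise_free(
    group_rates = dplyr::mutate(default_rates_fixture(), rate_per_day = 0))
  fame <- simulate_fame_table(truth, seed = 3)
  expect_equal(fame$atpct_labelled, fame$atpct_natural, tolerance = 1e-12)
  dna <- simulate_dna_table(truth, seed = 3)
  expect_equal(dna$atpct_labelled, dna$atpct_natural, tolerance = 1e-12)
})

test_that("unphysical truth (pool turning over more than once) errors", {
  truth <- truth_noise_free(
    group_rates = dplyr::mutate(default_rates_fixture(), rate_per_day = 0.6))
  expect_error(simulate_fame_table(truth, seed = 1),
               class = "vs_truth_error")
})

test_that("zero respiration yields zero headspace accumulation, and truth CUE is recovered", {
  truth0 <- truth_noise_free(
    respiration = dplyr::mutate(vs_truth()$respiration, respiration = 0))
  hs0 <- simulate_headspace(truth0, seed = 2)
  expect_equal(hs0$co2_t1, hs0$co2_t0, tolerance = 1e-12)

  # 162.5 ng C /g/h truth, 0.8 g, 25 mL, 20 C, 48 h -> ~500 ppm rise
  truth1 <- truth_noise_free(
    respiration = dplyr::mutate(vs_truth()$respiration, respiration = 162.5))
  hs1 <- simulate_headspace(truth1, seed = 2, headspace_volume = 25)
  amb <- dplyr::inner_join(
    hs1, dplyr::filter(simulate_metadata(truth1), .data$treatment == "ambient"),
    by = "sample_id")
  expect_equal(unique(round(amb$co2_t1 - amb$co2_t0, 6)), 500,
               tolerance = 1e-3)

  # noise-free pipeline returns the truth CUE exactly
  ds <- vs_simulate_dataset(truth_noise_free(), seed = 21)
  res <- vs_run_pipeline(ds, quiet = TRUE)
  chk <- dplyr::inner_join(res$physiology, ds$expected, by = "sample_id",
                           suffix = c("", "_true"))
  expect_equal(chk$cue, chk$cue_true, tolerance = 1e-9)
})
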