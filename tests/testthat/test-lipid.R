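test_that("newly produced fatty-acid C matches the hand-evaluated tracer equation", {
  rec <- tibble::tibble(sample_id = "s1", marker = "16:0", fraction = "plfa",
                        atpct_labelled = 0.207, atpct_natural = 0.0136,
                        fa_c = 100)
  out <- fa_c_produced(rec, soil_water = 16.1, config = vs_config(a_w = 0.71))
  hand <- (0.207 - 0.0136) / (0.71 * 16.1) * 100
  expect_equal(out$fa_c_produced, hand, tolerance = 1e-12)
  expect_equal(out$fa_c_produced, 1.692, tolerance = 1e-3)

  # no enrichment, no production
  rec0 <- dplyr::mutate(rec, atpct_labelled = atpct_natural)
  expect_equal(fa_c_produced(rec0, 16.1)$fa_c_produced, 0)

  # production is exactly linear in 1 / a_w
  half <- fa_c_produced(rec, 16.1, vs_config(a_w = 0.355))
  expect_equal(half$fa_c_produced, 2 * out$fa_c_produced, tolerance = 1e-12)
})

test_that("negative excess enrichment clamps to zero and is flagged", {
  rec <- tibble::tibble(sample_id = "s1", marker = "16:0", fraction = "plfa",
                        atpct_labelled = 0.0130, atpct_natural = 0.0136,
                        fa_c = 100)
  out <- fa_c_produced(rec, 16.1)
  expect_equal(out$fa_c_produced, 0)
  expect_true(out$clamped)
  raw <- fa_c_produced(rec, 16.1,
                       vs_config(clamp_negative_enrichment = FALSE))
  expect_lt(raw$fa_c_produced, 0)
  expect_error(fa_c_produced(rec, -1), class = "vs_domain_error")
})

test_that("community growth follows the produced-fraction times biomass over time", {
  fame <- tiny_fame()
  meta <- tiny_meta()
  fx <- fa_c_produced(fame, 16.1)
  cg <- community_growth(fx, meta)
  frac <- sum(fx$fa_c_produced) / sum(fx$fa_c)
  expect_equal(cg$fraction_new, frac, tolerance = 1e-12)
  expect_equal(cg$growth, frac * 1000 * 1000 / 48, tolerance = 1e-12)

  # anchor: fraction-new 0.016919 with 1000 ug biomass over 48 h
  cg2 <- tibble::tibble(sample_id = "s1", fraction = "plfa",
                        fa_c = 1000, fa_c_produced = 16.919,
                        clamped = FALSE, marker = "x") |>
    community_growth(meta)
  expect_equal(cg2$growth, 352.5, tolerance = 1e-3)
  expect_equal(cg2$ms_growth_per_h, 3.525e-4, tolerance = 1e-3)
  expect_equal(cg2$ms_growth_per_day, 8.4595e-3, tolerance = 1e-4)

  # doubling biomass doubles growth
  cg3 <- community_growth(fx, dplyr::mutate(meta,
                                            microbial_biomass_c = 2000))
  expect_equal(cg3$growth, 2 * cg$growth, tolerance = 1e-12)

  # zero total fatty-acid C is a degenerate sample
  expect_error(
    community_growth(dplyr::mutate(fx, fa_c = 0), meta),
    class = "vs_degenerate_sample_error")
})

test_that("community produced C equals the sum over marker-level produced C", {
  truth <- truth_noise_free()
  ds <- vs_simulate_dataset(truth, seed = 5)
  res <- vs_run_pipeline(ds, quiet = TRUE)
  per_sample <- res$fame_fluxes |>
    dplyr::group_by(.data$sample_id, .data$fraction) |>
    dplyr::summarise(tot = sum(.data$fa_c_produced), .groups = "drop")
  joined <- dplyr::inner_join(per_sample, res$lipid_community,
                              by = c("sample_id", "fraction"))
  expect_equal(joined$tot, joined$fa_c_produced, tolerance = 1e-12)
})

test_that("group rates divide group production by group pool and time", {
  fame <- tiny_fame()
  meta <- tiny_meta()
  fx <- fa_c_produced(fame, 16.1)
  gr <- mass_specific_rates(fx, meta, quiet = TRUE)

  fungi <- fx[fx$marker == "18:2w6,9", ]
  expect_equal(
    gr$ms_rate_per_h[gr$group == "fungi"],
    fungi$fa_c_produced / fungi$fa_c / 48, tolerance = 1e-12)
  expect_equal(gr$ms_rate_per_day, gr$ms_rate_per_h * 24, tolerance = 1e-12)
  expect_equal(gr$ms_rate_mg_g_h, gr$ms_rate_per_h * 1000, tolerance = 1e-12)
  # gram_positive_sum present (i15:0 is its only member here)
  expect_true("gram_positive_sum" %in% gr$group)

  # all at natural abundance -> all rates zero
  fx0 <- fa_c_produced(dplyr::mutate(fame, atpct_labelled = atpct_natural),
                       16.1)
  gr0 <- mass_specific_rates(fx0, meta, quiet = TRUE)
  expect_true(all(gr0$ms_rate_per_day == 0))
})

test_that("fungi to bacteria ratio uses gram sums only and scales correctly", {
  gv <- tibble::tibble(group = c("fungi", "gram_positive", "gram_negative",
                                 "amf", "general"),
                       ms_rate_per_day = c(2, 1, 1, 100, 100))
  expect_equal(fungi_to_bacteria(gv), 1)
  gv0 <- dplyr::mutate(gv,
                       ms_rate_per_day = replace(ms_rate_per_day, 1, 0))
  expect_equal(fungi_to_bacteria(gv0), 0)
  # homogeneity: proportional change leaves the ratio unchanged
  gv2 <- dplyr::mutate(gv, ms_rate_per_day = 3.7 * ms_rate_per_day)
  expect_equal(fungi_to_bacteria(gv2), fungi_to_bacteria(gv))
  # halving bacteria while fungi unchanged doubles the ratio
  gvh <- dplyr::mutate(gv, ms_rate_per_day = ifelse(
    group %in% c("gram_positive", "gram_negative"),
    ms_rate_per_day / 2, ms_rate_per_day))
  expect_equal(fungi_to_bacteria(gvh), 2 * fungi_to_bacteria(gv))
  expect_error(
    fungi_to_bacteria(dplyr::filter(gv, group == "fungi")),
    class = "vs_undefined_ratio_error")
})

test_that("storage percentage compares NLFA to PLFA production of shared markers", {
  fame <- dplyr::bind_rows(
    tiny_fame(),
    tibble::tibble(sample_id = "s1",
                   marker = c("18:2w6,9", "16:0"), fraction = "nlfa",
                   atpct_labelled = c(0.207, 0.0136), atpct_natural = 0.0136,
                   fa_c = c(228, 50)))
  fx <- fa_c_produced(fame, 16.1)
  sp <- nlfa_storage_pct(fx, quiet = TRUE)
  fungal <- sp[sp$group == "fungi", ]
  # NLFA produced = excess/denominator * 228; PLFA same excess * 100 -> 228%
  expect_equal(fungal$nlfa_to_plfa_pct, 228, tolerance = 1e-9)
  # zero NLFA production -> 0%
  expect_equal(sp$nlfa_to_plfa_pct[sp$group == "general"], 0)
  # markers only present in one fraction (i15:0, 16:1w7) never enter
  expect_false("gram_positive" %in% sp$group)
  expect_false("gram_negative" %in% sp$group)
})
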