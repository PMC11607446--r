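test_that("paired t-test matches hand computation and handles degeneracies", {
  # mean difference zero -> t = 0, p = 1
  out0 <- paired_t(c(1, 2, 3), c(1.1, 2.0, 2.9))
  expect_equal(out0$statistic, 0, tolerance = 1e-12)
  expect_equal(out0$p_value, 1, tolerance = 1e-12)

  # d = (-1, 0, -1, -1): mean -0.75, sd 0.5 -> t = -3, df = 3
  out <- paired_t(c(1, 2, 3, 4), c(2, 2, 4, 5))
  expect_equal(out$statistic, -3, tolerance = 1e-12)
  expect_equal(out$df, 3)
  expect_equal(out$p_value, 2 * stats::pt(-3, 3), tolerance = 1e-12)

  expect_error(paired_t(c(1, 2, 3), c(0, 1, 2)),
               class = "vs_degenerate_error")
  expect_error(paired_t(1, 2), class = "vs_data_error")
  # identical vectors: zero difference everywhere is a defined t = 0
  expect_equal(paired_t(c(1, 2), c(1, 2))$statistic, 0)
})

test_that("paired t agrees with the brute-force formula on random datasets", {
  for (i in 1:200) {
    set.seed(i)
    n <- sample(3:12, 1)
    x <- stats::rnorm(n, 10, 3)
    y <- x + stats::rnorm(n, 0.5, 1)
    out <- paired_t(x, y)
    d <- x - y
    t_ref <- mean(d) / (sd(d) / sqrt(n))
    expect_equal(out$statistic, t_ref, tolerance = 1e-10)
    expect_equal(out$df, n - 1)
    expect_equal(out$p_value, 2 * stats::pt(-abs(t_ref), n - 1),
                 tolerance = 1e-10)
  }
})

test_that("treatment contrasts recover constructed percent and fold changes", {
  d <- tidyr::expand_grid(treatment = vs_treatment_levels(),
                          phase = "drought", rep = 1:4) |>
    dplyr::mutate(resp = dplyr::case_when(
      treatment %in% c("ambient", "future") ~ 100,
      TRUE ~ 52))
  cc <- treatment_contrasts(d, "resp")
  pooled <- cc$contrasts[cc$contrasts$climate == "pooled", ]
  expect_equal(pooled$percent_change, -48, tolerance = 1e-12)
  expect_equal(cc$cells$n, rep(4, 4))

  # identical means -> exactly 0% change
  same <- dplyr::mutate(d, resp = 7)
  cc0 <- treatment_contrasts(same, "resp")
  expect_true(all(cc0$contrasts$percent_change == 0))
  expect_true(all(cc0$contrasts$fold_change == 1))

  # 5.8-fold increase under drought
  fold <- dplyr::mutate(d, resp = ifelse(
    treatment %in% c("drought", "future_drought"), 580, 100))
  ccf <- treatment_contrasts(fold, "resp")
  expect_equal(ccf$contrasts$fold_change[ccf$contrasts$climate == "pooled"],
               5.8, tolerance = 1e-12)

  # contrasts are sign-consistent with the mean ordering
  expect_true(all(sign(cc$contrasts$percent_change) ==
                    sign(cc$contrasts$drought_mean -
                           cc$contrasts$control_mean)))
})

test_that("missing cells drop contrasts with a notice rather than failing", {
  d <- tibble::tibble(treatment = rep(c("ambient", "drought"), each = 3),
                      phase = "drought", resp = c(10, 11, 12, 5, 6, 7))
  expect_message(cc <- treatment_contrasts(d, "resp"), "omitted")
  expect_equal(cc$contrasts$climate, "ambient")
  expect_error(treatment_contrasts(d, "nope"), class = "vs_schema_error")
})

test_that("turnover table uses treatment-mean growth, not mean of turnovers", {
  meta <- dplyr::bind_rows(tiny_meta("a"), tiny_meta("b"))
  phys <- tibble::tibble(
    sample_id = c("a", "b"), tracer = "plfa_2h",
    growth = c(200, 600), respiration = 300, uptake = NA, cue = NA,
    turnover_days = turnover_days(1000, c(200, 600)),
    turnover_days_rounded = NA, ms_growth_per_day = NA)
  tt <- turnover_table(phys, meta)
  expect_equal(tt$turnover_days, 1000 * 1000 / (400 * 24), tolerance = 1e-12)
  # mean of per-sample turnovers is larger (Jensen): both are reported
  expect_gt(tt$mean_of_sample_turnover, tt$turnover_days)
  expect_equal(tt$turnover_days_rounded, round(tt$turnover_days))
})
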