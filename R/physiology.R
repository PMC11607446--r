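#' Soil respiration rate from headspace CO2 accumulation
#'
#' Ideal-gas conversion of the ppm rise in vial headspace CO2 to a carbon
#' flux: `mol = P * V * dppm*1e-6 / (R * T)`, then to
#' ng C g\eqn{^{-1}} dry soil h\eqn{^{-1}} via 12.011 g C/mol, the soil dry
#' mass and the elapsed time. A CO2 *drop* larger than `leak_tol` ppm is
#' flagged (leak suspicion) but the rate is still returned.
#'
#' @param headspace Tibble `sample_id, co2_t0, co2_t1` (ppm), optional
#'   `headspace_volume` (mL), `elapsed` (h), `pressure` (Pa).
#' @param meta Metadata with `sample_id, soil_dry_mass` (g), `temperature`
#'   (deg C) and `incubation_time` (used when `elapsed` is absent).
#' @param config A [vs_config()] supplying default headspace volume and
#'   pressure.
#' @param leak_tol ppm of tolerated negative drift before flagging.
#' @return Tibble `sample_id, respiration` (ng C g^-1 h^-1), `leak_flag`.
#' @export
respiration_rate <- function(headspace, meta, config = vs_config(),
                             leak_tol = 5) {
  hs <- tibble::as_tibble(headspace)
  req <- c("sample_id", "co2_t0", "co2_t1")
  miss <- setdiff(req, names(hs))
  if (length(miss)) {
    abort(paste0("headspace table is missing column(s): ",
                 paste(miss, collapse = ", ")), class = "vs_schema_error")
  }
  meta <- tibble::as_tibble(meta)
  hs <- dplyr::left_join(
    hs, dplyr::select(meta, "sample_id", "soil_dry_mass", "temperature",
                      "incubation_time"),
    by = "sample_id")
  if (!"headspace_volume" %in% names(hs)) {
    hs$headspace_volume <- config$headspace_volume
  }
  if (!"elapsed" %in% names(hs)) hs$elapsed <- hs$incubation_time
  if (!"pressure" %in% names(hs)) hs$pressure <- config$pressure
  gas_const <- 8.31446261815324
  hs |>
    dplyr::mutate(
      dppm = .data$co2_t1 - .data$co2_t0,
      leak_flag = .data$dppm < -leak_tol,
      mol_co2 = .data$pressure * (.data$headspace_volume * 1e-6) *
        (.data$dppm * 1e-6) / (gas_const * (.data$temperature + 273.15)),
      respiration = .data$mol_co2 * 12.011e9 / .data$soil_dry_mass /
        .data$elapsed
    ) |>
    dplyr::select("sample_id", "respiration", "leak_flag")
}

#' Carbon use efficiency
#'
#' The anabolic fraction of carbon uptake, `CUE = growth / (growth +
#' respiration)`; undefined (NA, with a warning) when both rates are zero.
#'
#' @param growth,respiration Rates on a common scale
#'   (ng C g\eqn{^{-1}} h\eqn{^{-1}}), vectorised.
#' @return CUE as a fraction in \[0, 1\] for non-negative inputs.
#' @export
cue <- function(growth, respiration) {
  uptake <- growth + respiration
  undef <- uptake == 0
  if (any(undef, na.rm = TRUE)) {
    warn("growth and respiration both zero: CUE undefined (NA).")
  }
  out <- growth / uptake
  out[undef] <- NA_real_
  out
}

#' Microbial biomass turnover time
#'
#' Days for the community to replace its biomass carbon once:
#' \deqn{T = \frac{Microbial\,BM\,C}{Growth \times 24},}
#' with biomass in ug C g\eqn{^{-1}} and growth in ng C g\eqn{^{-1}}
#' h\eqn{^{-1}}; equivalently the reciprocal of the daily mass-specific
#' growth rate. Non-positive growth yields `NA` with a warning.
#'
#' @param biomass_c Microbial biomass C, ug C per g dry soil.
#' @param growth Growth rate, ng C per g dry soil per hour.
#' @return Turnover time in days.
#' @export
turnover_days <- function(biomass_c, growth) {
  undef <- !(growth > 0)
  if (any(undef, na.rm = TRUE)) {
    warn("non-positive growth: turnover time undefined (NA).")
  }
  out <- biomass_c * 1000 / (growth * 24)
  out[undef] <- NA_real_
  out
}

#' Per-sample physiology table for one tracer
#'
#' Joins a growth table with respiration and derives uptake
#' (growth + respiration), CUE and turnover time.
#'
#' @param growth_tbl Output of [community_growth()] (PLFA rows are used) or
#'   [growth_dna()].
#' @param resp_tbl Output of [respiration_rate()].
#' @param meta Sample metadata.
#' @param tracer `"plfa_2h"` or `"dna_18o"`.
#' @return Tibble, one row per sample: `sample_id, tracer, growth,
#'   respiration, uptake, cue, turnover_days, turnover_days_rounded,
#'   ms_growth_per_day`.
#' @export
physiology_table <- function(growth_tbl, resp_tbl, meta,
                             tracer = c("plfa_2h", "dna_18o")) {
  tracer <- match.arg(tracer)
  g <- tibble::as_tibble(growth_tbl)
  if ("fraction" %in% names(g)) g <- dplyr::filter(g, .data$fraction == "plfa")
  g |>
    dplyr::select("sample_id", "growth", "ms_growth_per_day") |>
    dplyr::left_join(tibble::as_tibble(resp_tbl), by = "sample_id") |>
    dplyr::left_join(
      dplyr::select(tibble::as_tibble(meta), "sample_id",
                    "microbial_biomass_c"),
      by = "sample_id") |>
    dplyr::mutate(
      tracer = tracer,
      uptake = .data$growth + .data$respiration,
      cue = cue(.data$growth, .data$respiration),
      turnover_days = turnover_days(.data$microbial_biomass_c, .data$growth),
      turnover_days_rounded = round(.data$turnover_days)
    ) |>
    dplyr::select("sample_id", "tracer", "growth", "respiration", "uptake",
                  "cue", "turnover_days", "turnover_days_rounded",
                  "ms_growth_per_day")
}
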