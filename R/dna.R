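#' DNA newly produced over the incubation from 18O incorporation
#'
#' \deqn{DNA_{produced} = O_{DNA\,extr} \times
#'   \frac{at\%^{18}O_{labelled} - at\%^{18}O_{nat}}{at\%^{18}O_{soil\,water}}
#'   \times \frac{100}{31.21},}
#' in ug DNA per g dry soil: the excess 18O in the extract, scaled from
#' oxygen to whole DNA by the mean DNA oxygen content (31.21 % by default).
#' No assimilation constant is applied to the DNA tracer.
#'
#' @param dna DNA table: `sample_id, o_dna_extract` (ug O/g),
#'   `atpct_labelled, atpct_natural, total_dna` (ug/g), and
#'   `soil_water_atpct` unless supplied via `soil_water`.
#' @param soil_water Optional: single at% or tibble
#'   `sample_id, soil_water_atpct` with the time-averaged 18O soil-water
#'   enrichment.
#' @param config A [vs_config()] (supplies `dna_oxygen_fraction` and the
#'   clamping toggle).
#' @return Input tibble plus `fraction_new`, `clamped` and `dna_produced`
#'   (ug per g dry soil).
#' @export
dna_produced <- function(dna, soil_water = NULL, config = vs_config()) {
  dna <- tibble::as_tibble(dna)
  req <- c("sample_id", "o_dna_extract", "atpct_labelled", "atpct_natural",
           "total_dna")
  miss <- setdiff(req, names(dna))
  if (length(miss)) {
    abort(paste0("DNA table is missing column(s): ",
                 paste(miss, collapse = ", ")), class = "vs_schema_error")
  }
  if (!is.null(soil_water)) {
    if (is.data.frame(soil_water)) {
      dna$soil_water_atpct <- NULL
      dna <- dplyr::left_join(dna,
                              dplyr::select(tibble::as_tibble(soil_water),
                                            "sample_id", "soil_water_atpct"),
                              by = "sample_id")
    } else {
      dna$soil_water_atpct <- soil_water
    }
  }
  if (!"soil_water_atpct" %in% names(dna) || anyNA(dna$soil_water_atpct)) {
    abort("every DNA sample needs a soil-water 18O enrichment.",
          class = "vs_data_error")
  }
  k <- tracer_fraction_new(dna$atpct_labelled, dna$atpct_natural,
                           dna$soil_water_atpct, assimilation = 1,
                           clamp = config$clamp_negative_enrichment)
  dna$fraction_new <- k$fraction_new
  dna$clamped <- k$clamped
  dna$dna_produced <- dna$o_dna_extract * k$fraction_new *
    100 / config$dna_oxygen_fraction
  dna
}

#' DNA-based microbial growth rate
#'
#' Converts the newly produced DNA fraction to carbon units via the ratio of
#' microbial biomass C to total DNA, expressed per hour so it can be combined
#' with hourly respiration:
#' \deqn{Growth_{DNA} = \frac{DNA_{produced}}{Total\,DNA}
#'   \times Microbial\,BM\,C / time,}
#' in ng C g\eqn{^{-1}} dry soil h\eqn{^{-1}}.
#'
#' @param dna Output of [dna_produced()].
#' @param meta Sample metadata (`sample_id, microbial_biomass_c` ug C/g,
#'   `incubation_time` h).
#' @return One row per sample with `growth` plus mass-specific rates
#'   (`ms_growth_per_h`, `ms_growth_mg_g_h`, `ms_growth_per_day`).
#' @export
growth_dna <- function(dna, meta) {
  if (any(dna$total_dna <= 0)) {
    abort("sample with zero total DNA.", class = "vs_degenerate_sample_error")
  }
  dna |>
    dplyr::left_join(
      dplyr::select(tibble::as_tibble(meta), "sample_id",
                    "microbial_biomass_c", "incubation_time"),
      by = "sample_id") |>
    dplyr::mutate(
      fraction_new_dna = .data$dna_produced / .data$total_dna,
      growth = .data$fraction_new_dna * .data$microbial_biomass_c * 1000 /
        .data$incubation_time,
      ms_growth_per_h = .data$fraction_new_dna / .data$incubation_time,
      ms_growth_mg_g_h = .data$ms_growth_per_h * 1000,
      ms_growth_per_day = .data$ms_growth_per_h * 24
    )
}
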