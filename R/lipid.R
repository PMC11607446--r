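#' Newly produced carbon per fatty-acid marker
#'
#' For each record, the carbon newly synthesised into that fatty acid over
#' the incubation:
#' \deqn{FA\,C_{produced} = \frac{at\%_{labelled} - at\%_{natural}}
#'   {a_w \cdot at\%_{soil\,water}} \times FA\,C,}
#' in ng C per g dry soil. Internal-standard rows must already be excluded
#' (the readers and [quantify_fa_carbon()] drop them).
#'
#' @param fame Fatty-acid tibble: `sample_id, marker, fraction` (plfa/nlfa),
#'   `atpct_labelled, atpct_natural, fa_c`.
#' @param soil_water Either a single at% value, or a tibble
#'   `sample_id, soil_water_atpct` giving the time-averaged 2H soil-water
#'   enrichment for each sample.
#' @param config A [vs_config()] (supplies `a_w` and the clamping toggle).
#' @return Input tibble plus `fraction_new`, `clamped` and `fa_c_produced`
#'   (ng C per g dry soil over the incubation).
#' @export
fa_c_produced <- function(fame, soil_water, config = vs_config()) {
  fame <- tibble::as_tibble(fame)
  req <- c("sample_id", "marker", "fraction", "atpct_labelled",
           "atpct_natural", "fa_c")
  miss <- setdiff(req, names(fame))
  if (length(miss)) {
    abort(paste0("fatty-acid table is missing column(s): ",
                 paste(miss, collapse = ", ")), class = "vs_schema_error")
  }
  if (is.data.frame(soil_water)) {
    fame <- dplyr::left_join(fame,
                             dplyr::select(tibble::as_tibble(soil_water),
                                           "sample_id", "soil_water_atpct"),
                             by = "sample_id")
    if (anyNA(fame$soil_water_atpct)) {
      abort("some samples have no soil-water enrichment value.",
            class = "vs_data_error")
    }
  } else {
    fame$soil_water_atpct <- soil_water
  }
  k <- tracer_fraction_new(fame$atpct_labelled, fame$atpct_natural,
                           fame$soil_water_atpct, assimilation = config$a_w,
                           clamp = config$clamp_negative_enrichment)
  fame$fraction_new <- k$fraction_new
  fame$clamped <- k$clamped
  fame$fa_c_produced <- k$fraction_new * fame$fa_c
  fame
}

#' Community-level lipid production and growth per sample
#'
#' Sums marker-level production to PLFA (and NLFA) community totals and
#' converts the newly produced PLFA fraction to a biomass growth rate:
#' \deqn{Growth_{PLFA} = \frac{PLFA\,C_{produced}}{Total\,PLFA\,C}
#'   \times Microbial\,BM\,C / time,}
#' with microbial biomass C in ng for unit consistency, giving
#' ng C g\eqn{^{-1}} dry soil h\eqn{^{-1}}. Mass-specific growth is the same
#' quantity per unit biomass C: numerically `fraction_new / time` (h^-1),
#' reported also in mg C g\eqn{^{-1}} mic C h\eqn{^{-1}} (x1000) and
#' day\eqn{^{-1}} (x24).
#'
#' @param fluxes Output of [fa_c_produced()].
#' @param meta Sample metadata (`sample_id, microbial_biomass_c` in ug C/g,
#'   `incubation_time` in h).
#' @return One row per sample and lipid fraction: totals, produced C, growth
#'   rate and mass-specific rates, plus the count of clamped records.
#' @export
community_growth <- function(fluxes, meta) {
  meta <- tibble::as_tibble(meta)
  out <- fluxes |>
    dplyr::group_by(.data$sample_id, .data$fraction) |>
    dplyr::summarise(
      total_fa_c = sum(.data$fa_c),
      fa_c_produced = sum(.data$fa_c_produced),
      n_markers = dplyr::n(),
      n_clamped = sum(.data$clamped),
      .groups = "drop"
    ) |>
    dplyr::left_join(
      dplyr::select(meta, "sample_id", "microbial_biomass_c",
                    "incubation_time"),
      by = "sample_id")
  if (any(out$total_fa_c <= 0)) {
    abort("sample with zero total fatty-acid C; cannot form produced fraction.",
          class = "vs_degenerate_sample_error")
  }
  out |>
    dplyr::mutate(
      fraction_new = .data$fa_c_produced / .data$total_fa_c,
      # biomass ug -> ng (x1000)
      growth = .data$fraction_new * .data$microbial_biomass_c * 1000 /
        .data$incubation_time,
      ms_growth_per_h = .data$fraction_new / .data$incubation_time,
      ms_growth_mg_g_h = .data$ms_growth_per_h * 1000,
      ms_growth_per_day = .data$ms_growth_per_h * 24
    )
}

#' Group-specific mass-specific production rates
#'
#' For each microbial group g in each sample and lipid fraction:
#' \deqn{rate_g = \frac{\sum_{i \in g} FA\,C_{produced,i}}
#'   {\sum_{i \in g} FA\,C_i} \; / \; time,}
#' in h\eqn{^{-1}} (also given x1000 as mg C g\eqn{^{-1}} group C
#' h\eqn{^{-1}} and x24 as day\eqn{^{-1}}). Groups follow the marker registry;
#' a `gram_positive_sum` row (gram-positive plus actinobacteria markers) is
#' added since drought contrasts of gram-positive bacteria are reported on
#' that union. Groups with zero fatty-acid C are omitted with a notice, never
#' reported as rate 0.
#'
#' @param fluxes Output of [fa_c_produced()].
#' @param meta Sample metadata with `incubation_time`.
#' @param registry Marker registry from [vs_registry()].
#' @param quiet Suppress the unknown-marker/empty-group notices.
#' @return Tibble `sample_id, fraction, group, group_fa_c, group_fa_c_produced,
#'   ms_rate_per_h, ms_rate_mg_g_h, ms_rate_per_day`.
#' @export
mass_specific_rates <- function(fluxes, meta, registry = vs_registry(),
                                quiet = FALSE) {
  asg <- assign_markers(fluxes$marker, registry = registry, quiet = quiet)
  fx <- dplyr::bind_cols(fluxes,
                         asg[c("group", "in_gram_positive_sum")])
  gp_sum <- fx |>
    dplyr::filter(.data$in_gram_positive_sum) |>
    dplyr::mutate(group = "gram_positive_sum")
  out <- dplyr::bind_rows(fx, gp_sum) |>
    dplyr::group_by(.data$sample_id, .data$fraction, .data$group) |>
    dplyr::summarise(
      group_fa_c = sum(.data$fa_c),
      group_fa_c_produced = sum(.data$fa_c_produced),
      .groups = "drop"
    ) |>
    dplyr::left_join(
      dplyr::select(tibble::as_tibble(meta), "sample_id", "incubation_time"),
      by = "sample_id")
  empty <- out |> dplyr::filter(.data$group_fa_c <= 0)
  if (nrow(empty) && !quiet) {
    inform(paste0("omitting group(s) with zero fatty-acid C: ",
                  paste(unique(empty$group), collapse = ", ")))
  }
  out |>
    dplyr::filter(.data$group_fa_c > 0) |>
    dplyr::mutate(
      ms_rate_per_h = .data$group_fa_c_produced / .data$group_fa_c /
        .data$incubation_time,
      ms_rate_mg_g_h = .data$ms_rate_per_h * 1000,
      ms_rate_per_day = .data$ms_rate_per_h * 24
    ) |>
    dplyr::select(-"incubation_time")
}

#' Fungi to bacteria ratio
#'
#' Fungal value over the sum of gram-positive (including actinobacteria
#' markers) and gram-negative values; the AMF and general groups enter
#' neither numerator nor denominator.
#'
#' @param group_values Tibble with a `group` column and the value column
#'   named by `value`; typically one sample's rows of
#'   [mass_specific_rates()] output, or group abundances.
#' @param value Name of the value column (default `"ms_rate_per_day"`).
#' @return A single ratio.
#' @export
fungi_to_bacteria <- function(group_values, value = "ms_rate_per_day") {
  gv <- tibble::as_tibble(group_values)
  pick <- function(g) sum(gv[[value]][gv$group == g])
  fungi <- pick("fungi")
  bact <- if ("gram_positive_sum" %in% gv$group) {
    pick("gram_positive_sum") + pick("gram_negative")
  } else {
    pick("gram_positive") + pick("actinobacteria") + pick("gram_negative")
  }
  if (!is.finite(bact) || bact <= 0) {
    abort("bacterial denominator is zero; fungi:bacteria ratio undefined.",
          class = "vs_undefined_ratio_error")
  }
  fungi / bact
}

#' Storage investment: newly produced NLFA relative to PLFA
#'
#' Per group, 100 x the sum of newly produced NLFA C over the sum of newly
#' produced PLFA C, restricted to markers measured in both lipid fractions so
#' that numerator and denominator cover the same biomarkers. Values above
#' 100% mean more carbon flowed into storage lipids than into membrane
#' lipids of that group.
#'
#' @param fluxes Output of [fa_c_produced()] containing both fractions.
#' @param registry Marker registry.
#' @param quiet Suppress notices.
#' @return Tibble `sample_id, group, nlfa_produced, plfa_produced,
#'   nlfa_to_plfa_pct`; groups whose PLFA production is zero get `NA` with a
#'   notice.
#' @export
nlfa_storage_pct <- function(fluxes, registry = vs_registry(), quiet = FALSE) {
  fx <- dplyr::bind_cols(
    fluxes,
    assign_markers(fluxes$marker, registry = registry, quiet = quiet)["group"])
  fx <- dplyr::mutate(fx, marker_norm = normalize_marker(.data$marker))
  shared <- fx |>
    dplyr::distinct(.data$sample_id, .data$marker_norm, .data$fraction) |>
    dplyr::count(.data$sample_id, .data$marker_norm) |>
    dplyr::filter(.data$n == 2) |>
    dplyr::select(-"n")
  out <- fx |>
    dplyr::inner_join(shared, by = c("sample_id", "marker_norm")) |>
    dplyr::group_by(.data$sample_id, .data$group, .data$fraction) |>
    dplyr::summarise(produced = sum(.data$fa_c_produced), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "fraction", values_from = "produced",
                       names_glue = "{fraction}_produced")
  for (col in c("plfa_produced", "nlfa_produced")) {
    if (!col %in% names(out)) out[[col]] <- numeric(nrow(out))
  }
  out <- out |>
    dplyr::mutate(
      nlfa_to_plfa_pct = dplyr::if_else(
        .data$plfa_produced > 0,
        100 * .data$nlfa_produced / .data$plfa_produced,
        NA_real_)
    )
  if (anyNA(out$nlfa_to_plfa_pct) && !quiet) {
    inform("group(s) with zero PLFA production: storage percentage undefined (NA).")
  }
  out
}
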