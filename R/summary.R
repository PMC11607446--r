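#' Two-sided paired t-test
#'
#' Used for the label-toxicity check: respiration of 2H-labelled vials paired
#' with the natural-abundance vials from the same plots. Thin wrapper over
#' [stats::t.test()] with `paired = TRUE`, returning a tidy one-row tibble.
#'
#' @param x,y Paired numeric vectors of equal length (n >= 2).
#' @return Tibble `estimate` (mean difference), `statistic` (t), `df`,
#'   `p_value`, `n`.
#' @export
#' @examples
#' paired_t(c(1, 2, 3, 4), c(2, 2, 4, 5))
paired_t <- function(x, y) {
  if (length(x) != length(y)) {
    abort("x and y must have equal length.", class = "vs_data_error")
  }
  if (length(x) < 2) {
    abort("need at least 2 pairs.", class = "vs_data_error")
  }
  d <- x - y
  if (sd(d) == 0) {
    if (mean(d) == 0) {
      return(tibble::tibble(estimate = 0, statistic = 0,
                            df = length(d) - 1, p_value = 1, n = length(d)))
    }
    abort("zero-variance differences with nonzero mean: t undefined.",
          class = "vs_degenerate_error")
  }
  tt <- t.test(x, y, paired = TRUE)
  tibble::tibble(
    estimate = unname(tt$estimate),
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value,
    n = length(x)
  )
}

#' Treatment-level summaries and drought contrasts
#'
#' Arithmetic cell means (phase x treatment) of a response, plus the
#' percent change caused by drought relative to the matching non-drought
#' climate (ambient vs drought; future vs future + drought) and a pooled
#' drought effect (the mean of the two climate-specific percent changes).
#' Negative `percent_change` means drought reduced the response. Fold changes
#' (`drought mean / control mean`) are also reported, the framing used for
#' storage-compound increases.
#'
#' @param data Tibble holding per-sample results with `treatment`, `phase`
#'   and the response column.
#' @param response Name of the response column (string).
#' @return List of two tibbles: `cells` (phase, treatment, mean, sd, n) and
#'   `contrasts` (phase, climate in ambient/future/pooled, control_mean,
#'   drought_mean, percent_change, fold_change).
#' @export
treatment_contrasts <- function(data, response) {
  data <- tibble::as_tibble(data)
  if (!response %in% names(data)) {
    abort(paste0("no column `", response, "` in data."),
          class = "vs_schema_error")
  }
  cells <- data |>
    dplyr::group_by(.data$phase, .data$treatment) |>
    dplyr::summarise(
      mean = mean(.data[[response]], na.rm = TRUE),
      sd = sd(.data[[response]], na.rm = TRUE),
      n = sum(!is.na(.data[[response]])),
      .groups = "drop")

  pair <- tibble::tibble(
    climate = c("ambient", "future"),
    control = c("ambient", "future"),
    droughted = c("drought", "future_drought"))

  one_phase <- function(ph) {
    cc <- dplyr::filter(cells, .data$phase == ph)
    rows <- purrr::pmap_dfr(pair, function(climate, control, droughted) {
      cm <- cc$mean[cc$treatment == control]
      dm <- cc$mean[cc$treatment == droughted]
      if (!length(cm) || !length(dm)) {
        inform(paste0("phase ", ph, ": missing cell for climate ", climate,
                      "; contrast omitted."))
        return(tibble::tibble())
      }
      tibble::tibble(phase = ph, climate = climate, control_mean = cm,
                     drought_mean = dm,
                     percent_change = 100 * (dm - cm) / cm,
                     fold_change = dm / cm)
    })
    if (nrow(rows) == 2) {
      rows <- dplyr::bind_rows(
        rows,
        tibble::tibble(phase = ph, climate = "pooled",
                       control_mean = mean(rows$control_mean),
                       drought_mean = mean(rows$drought_mean),
                       percent_change = mean(rows$percent_change),
                       fold_change = mean(rows$fold_change)))
    }
    rows
  }
  contrasts <- purrr::map_dfr(unique(cells$phase), one_phase)
  list(cells = cells, contrasts = contrasts)
}

#' Treatment-level turnover table
#'
#' Turnover times per phase x treatment computed from the treatment-mean
#' growth rate and treatment-mean biomass (the canonical, "rounded values"
#' presentation), alongside the mean of per-sample turnover times.
#'
#' @param physio Physiology tibble from [physiology_table()] joined with
#'   metadata columns `treatment` and `phase`; needs `growth`,
#'   `microbial_biomass_c` via `meta`.
#' @param meta Sample metadata.
#' @return Tibble `tracer, phase, treatment, turnover_days,
#'   turnover_days_rounded, mean_of_sample_turnover`.
#' @export
turnover_table <- function(physio, meta) {
  meta <- tibble::as_tibble(meta)
  physio |>
    dplyr::left_join(
      dplyr::select(meta, "sample_id", "treatment", "phase",
                    microbial_biomass_c2 = "microbial_biomass_c"),
      by = "sample_id") |>
    dplyr::group_by(.data$tracer, .data$phase, .data$treatment) |>
    dplyr::summarise(
      mean_growth = mean(.data$growth),
      mean_biomass = mean(.data$microbial_biomass_c2),
      mean_of_sample_turnover = mean(.data$turnover_days),
      .groups = "drop") |>
    dplyr::mutate(
      turnover_days = turnover_days(.data$mean_biomass, .data$mean_growth),
      turnover_days_rounded = round(.data$turnover_days)) |>
    dplyr::select("tracer", "phase", "treatment", "turnover_days",
                  "turnover_days_rounded", "mean_of_sample_turnover")
}
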