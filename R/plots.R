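#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an equilibration fit
#'
#' Observed water at% against time with the fitted exponential curve and the
#' window-average enrichment as a dashed reference line.
#'
#' @param object A `vs_equilibration_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vs_equilibration_fit <- function(object, ...) {
  grid <- tibble::tibble(
    time_h = seq(0, max(object$window, max(object$data$time_h)),
                 length.out = 200))
  grid$atom_percent <- predict(object, grid$time_h)
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$time_h, y = .data$atom_percent)) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = object$average_atpct,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Incubation time (h)",
                  y = "Soil water tracer (at%)",
                  title = sprintf("Equilibration fit: mean %.2f at%% over %g h",
                                  object$average_atpct, object$window)) +
    ggplot2::theme_minimal()
}

#' Plot a calibration model
#'
#' Known vs measured delta values of the standards with the fitted
#' normalization line.
#'
#' @param object A `vs_calibration`.
#' @param standards The standards table the model was fitted to (columns
#'   `measured_delta`, `known_delta`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vs_calibration <- function(object, standards, ...) {
  ggplot2::ggplot(standards,
                  ggplot2::aes(x = .data$measured_delta,
                               y = .data$known_delta)) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Measured δ (‰)", y = "Known δ (‰)",
                  title = "VSMOW normalization") +
    ggplot2::theme_minimal()
}

#' Plot group mass-specific production rates by treatment
#'
#' @param group_rates Output of [mass_specific_rates()].
#' @param meta Sample metadata (`sample_id, treatment, phase`).
#' @param fraction Lipid fraction to show.
#' @return A ggplot object (boxplots per group and treatment, facetted by
#'   phase).
#' @export
plot_group_rates <- function(group_rates, meta, fraction = "plfa") {
  d <- group_rates |>
    dplyr::filter(.data$fraction == !!fraction) |>
    dplyr::left_join(
      dplyr::select(tibble::as_tibble(meta), "sample_id", "treatment",
                    "phase"),
      by = "sample_id")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group,
                                  y = .data$ms_rate_per_day,
                                  fill = .data$treatment)) +
    ggplot2::geom_boxplot(outlier.size = 0.7) +
    ggplot2::facet_wrap(~phase) +
    ggplot2::labs(x = NULL,
                  y = expression("Mass-specific production (day"^-1*")"),
                  fill = "Treatment") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot community physiology by treatment
#'
#' @param physiology Output of [physiology_table()] (or the pipeline's
#'   `physiology` table).
#' @param meta Sample metadata.
#' @param response One of `"growth"`, `"respiration"`, `"cue"`,
#'   `"ms_growth_per_day"`, `"turnover_days"`.
#' @return A ggplot object.
#' @export
plot_physiology <- function(physiology, meta, response = "cue") {
  d <- physiology |>
    dplyr::left_join(
      dplyr::select(tibble::as_tibble(meta), "sample_id", "treatment",
                    "phase"),
      by = "sample_id")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$treatment,
                                  y = .data[[response]],
                                  fill = .data$treatment)) +
    ggplot2::geom_boxplot(outlier.size = 0.7) +
    ggplot2::facet_grid(tracer ~ phase) +
    ggplot2::labs(x = NULL, y = response) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot storage investment (NLFA:PLFA production percentage)
#'
#' @param storage_pct Output of [nlfa_storage_pct()].
#' @param meta Sample metadata.
#' @param groups Groups to display.
#' @return A ggplot object.
#' @export
plot_storage_investment <- function(storage_pct, meta, groups = "fungi") {
  d <- storage_pct |>
    dplyr::filter(.data$group %in% groups) |>
    dplyr::left_join(
      dplyr::select(tibble::as_tibble(meta), "sample_id", "treatment",
                    "phase"),
      by = "sample_id")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$treatment,
                                  y = .data$nlfa_to_plfa_pct,
                                  fill = .data$treatment)) +
    ggplot2::geom_boxplot(outlier.size = 0.7) +
    ggplot2::facet_grid(group ~ phase) +
    ggplot2::labs(x = NULL, y = "Newly produced NLFA : PLFA (%)") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
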