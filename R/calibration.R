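#' Convert delta notation to atom percent
#'
#' Two-isotope conversion between per-mil delta values on a reference scale
#' and atom percent of the heavy isotope:
#' \deqn{R = (\delta/1000 + 1)\,R_{std}, \quad at\% = 100\,R/(1 + R).}
#'
#' @param delta Numeric vector of per-mil delta values (must be > -1000).
#' @param r_std Heavy/light isotope ratio of the reference scale, e.g.
#'   `vs_config()$r_vsmow_2h` for delta-2H on VSMOW.
#' @return Atom percent, numeric vector in (0, 100).
#' @seealso [atom_percent_to_delta()] for the exact inverse.
#' @export
#' @examples
#' delta_to_atom_percent(0, 0.00015576)     # VSMOW itself: 0.015574 at%
#' delta_to_atom_percent(1000, 0.00015576)  # ratio doubles
delta_to_atom_percent <- function(delta, r_std) {
  stopifnot(is.numeric(delta), is.numeric(r_std), r_std > 0)
  if (any(delta <= -1000, na.rm = TRUE)) {
    abort("delta values must exceed -1000 per mil (R would be non-positive).",
          class = "vs_domain_error")
  }
  r <- (delta / 1000 + 1) * r_std
  100 * r / (1 + r)
}

#' @rdname delta_to_atom_percent
#' @param atom_percent Atom percent values in (0, 100).
#' @export
atom_percent_to_delta <- function(atom_percent, r_std) {
  stopifnot(is.numeric(atom_percent), is.numeric(r_std), r_std > 0)
  if (any(atom_percent <= 0 | atom_percent >= 100, na.rm = TRUE)) {
    abort("atom percent must lie strictly between 0 and 100.",
          class = "vs_domain_error")
  }
  f <- atom_percent / 100
  r <- f / (1 - f)
  (r / r_std - 1) * 1000
}

#' Fit a VSMOW normalization model from bracketing standards
#'
#' Ordinary least squares of known vs measured delta values of isotopic
#' standards (e.g. USGS70/USGS72 fatty-acid esters spanning delta-2H -183 to
#' +384 per mil), with a linear drift term over run position estimated in the
#' same least-squares problem when standards were measured at two or more run
#' positions (drift is 0 otherwise).
#'
#' @param standards Data frame with columns `known_delta`, `measured_delta`
#'   and optionally `compound` and `run_index` (integer sequence position).
#' @return An object of class `vs_calibration` with elements `slope`,
#'   `intercept` (per mil), `drift_per_index` (per mil per run position),
#'   `residual_sd` (per mil) and `n`.
#' @export
#' @examples
#' std <- tibble::tibble(known_delta = c(-183, 384),
#'                       measured_delta = c(-193, 374))
#' fit_calibration(std)
fit_calibration <- function(standards) {
  standards <- tibble::as_tibble(standards)
  req <- c("known_delta", "measured_delta")
  miss <- setdiff(req, names(standards))
  if (length(miss)) {
    abort(paste0("standards table is missing column(s): ",
                 paste(miss, collapse = ", ")), class = "vs_schema_error")
  }
  if (nrow(standards) < 2 || length(unique(standards$known_delta)) < 2) {
    abort("need at least two standards with distinct known delta values.",
          class = "vs_degenerate_fit_error")
  }
  if (length(unique(standards$measured_delta)) < 2) {
    abort("all standards have identical measured delta; calibration line is degenerate.",
          class = "vs_degenerate_fit_error")
  }
  # drift enters the same least-squares problem; identified only when
  # standards span >= 2 run positions and are not collinear with measured
  with_drift <- "run_index" %in% names(standards) &&
    length(unique(standards$run_index)) >= 2
  if (with_drift) {
    fit <- lm(known_delta ~ measured_delta + run_index, data = standards)
    cf <- coef(fit)
    if (anyNA(cf)) {
      with_drift <- FALSE
    } else {
      drift <- -unname(cf["run_index"])
    }
  }
  if (!with_drift) {
    fit <- lm(known_delta ~ measured_delta, data = standards)
    drift <- 0
  }
  slope <- unname(coef(fit)["measured_delta"])
  intercept <- unname(coef(fit)["(Intercept)"])
  res <- resid(fit)
  structure(
    list(slope = slope, intercept = intercept, drift_per_index = drift,
         residual_sd = if (length(res) > 2) sd(res) else 0,
         n = nrow(standards)),
    class = "vs_calibration"
  )
}

#' Apply a calibration model to raw delta values
#'
#' @param delta_raw Per-mil values against the working reference.
#' @param cal A `vs_calibration` from [fit_calibration()].
#' @param run_index Sequence positions of the measurements (default 0: no
#'   drift correction).
#' @return Per-mil values on the normalized (VSMOW) scale:
#'   `slope * delta_raw + intercept - drift_per_index * run_index`.
#' @export
apply_calibration <- function(delta_raw, cal, run_index = 0) {
  stopifnot(inherits(cal, "vs_calibration"))
  cal$slope * delta_raw + cal$intercept - cal$drift_per_index * run_index
}

#' @export
print.vs_calibration <- function(x, ...) {
  cat(sprintf(
    "<vs_calibration> slope %.5f, intercept %.3f permil, drift %.4f permil/index, residual sd %.3f permil (n = %d)\n",
    x$slope, x$intercept, x$drift_per_index, x$residual_sd, x$n))
  invisible(x)
}

#' @export
#' @importFrom generics tidy
tidy.vs_calibration <- function(x, ...) {
  tibble::tibble(
    term = c("slope", "intercept", "drift_per_index"),
    estimate = c(x$slope, x$intercept, x$drift_per_index)
  )
}

#' @export
#' @importFrom generics glance
glance.vs_calibration <- function(x, ...) {
  tibble::tibble(residual_sd = x$residual_sd, n = x$n)
}

#' Quantify fatty-acid carbon against the internal standard
#'
#' Converts per-compound chromatogram peak areas to carbon amounts per g dry
#' soil using the known carbon amount of the co-injected internal standard
#' (19:0 by default): `fa_c_i = area_i / area_IS * is_carbon / soil_dry_mass`.
#' The internal standard's own rows are dropped from the output (it carries no
#' biological signal and must not enter community sums).
#'
#' @param areas Data frame with columns `sample_id`, `marker`, `peak_area` and
#'   optionally `fraction`.
#' @param is_carbon ng C of internal standard added per sample (scalar or a
#'   data frame `sample_id`, `is_carbon`).
#' @param meta Sample metadata with `sample_id` and `soil_dry_mass` (g).
#' @param internal_standard Marker name of the internal standard.
#' @return Tibble `sample_id[, fraction], marker, fa_c` (ng C per g dry soil).
#' @export
quantify_fa_carbon <- function(areas, is_carbon, meta,
                               internal_standard = "19:0") {
  areas <- tibble::as_tibble(areas)
  req <- c("sample_id", "marker", "peak_area")
  miss <- setdiff(req, names(areas))
  if (length(miss)) {
    abort(paste0("peak-area table is missing column(s): ",
                 paste(miss, collapse = ", ")), class = "vs_schema_error")
  }
  if (any(areas$peak_area < 0, na.rm = TRUE)) {
    abort("peak areas must be non-negative.", class = "vs_domain_error")
  }
  is_norm <- normalize_marker(internal_standard)
  areas <- dplyr::mutate(areas, .marker_norm = normalize_marker(.data$marker))

  grp <- intersect(c("sample_id", "fraction"), names(areas))
  is_tab <- areas |>
    dplyr::filter(.data$.marker_norm == is_norm) |>
    dplyr::select(dplyr::all_of(grp), area_is = "peak_area")
  bad <- setdiff(
    unique(areas$sample_id),
    unique(is_tab$sample_id[is_tab$area_is > 0])
  )
  if (length(bad)) {
    abort(paste0("internal standard peak missing or zero in sample(s): ",
                 paste(bad, collapse = ", ")),
          class = "vs_quantification_error")
  }
  if (is.data.frame(is_carbon)) {
    is_tab <- dplyr::left_join(is_tab, tibble::as_tibble(is_carbon),
                               by = "sample_id")
  } else {
    is_tab$is_carbon <- is_carbon
  }
  areas |>
    dplyr::filter(.data$.marker_norm != is_norm) |>
    dplyr::left_join(is_tab, by = grp) |>
    dplyr::left_join(
      dplyr::select(tibble::as_tibble(meta), "sample_id", "soil_dry_mass"),
      by = "sample_id") |>
    dplyr::mutate(
      fa_c = .data$peak_area / .data$area_is * .data$is_carbon /
        .data$soil_dry_mass) |>
    dplyr::select(dplyr::all_of(grp), "marker", "fa_c")
}
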