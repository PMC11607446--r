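#' Soil-water enrichment by mass balance from source-water label loss
#'
#' During vapor-equilibration labelling the enriched water reservoir and the
#' soil water exchange isotopes only with each other, so the heavy-isotope
#' amount lost by the source pool appears in the soil pool:
#' \deqn{at\%_{soil}(t) = at\%_{soil,nat} +
#'   \frac{m_{source}}{m_{soil}}\,(at\%_{source}(0) - at\%_{source}(t)).}
#'
#' @param source_series Data frame with columns `time_h` and `atom_percent`
#'   for the source pool, starting at `time_h = 0`.
#' @param source_mass,soil_water_mass Water masses of the two pools (g).
#' @param soil_nat_atpct Natural-abundance at% of the soil water.
#' @return Tibble `time_h, atom_percent` for the soil pool.
#' @export
source_loss_to_soil_atpct <- function(source_series, source_mass,
                                      soil_water_mass, soil_nat_atpct) {
  s <- tibble::as_tibble(source_series)
  if (!all(c("time_h", "atom_percent") %in% names(s))) {
    abort("source series needs columns time_h and atom_percent.",
          class = "vs_schema_error")
  }
  if (source_mass <= 0 || soil_water_mass <= 0) {
    abort("water masses must be positive.", class = "vs_domain_error")
  }
  s <- dplyr::arrange(s, .data$time_h)
  if (s$time_h[1] != 0) {
    abort("source series must start at time 0.", class = "vs_data_error")
  }
  at0 <- s$atom_percent[1]
  soil <- soil_nat_atpct + source_mass / soil_water_mass *
    (at0 - s$atom_percent)
  if (any(soil < 0)) {
    abort("mass balance yields negative soil enrichment; check pool masses.",
          class = "vs_mass_balance_error")
  }
  tibble::tibble(time_h = s$time_h, atom_percent = soil)
}

#' Fit the water-vapor equilibration time course
#'
#' Least-squares fit of the negative exponential
#' \deqn{X(t) = X_{end} + (X_{start} - X_{end})\,e^{-bt}}
#' to an observed at% time series (either the decaying source-water series or
#' the rising soil-water series derived by mass balance). `b` (per hour) is a
#' soil-specific equilibration coefficient, bounded in `[1e-6, 1e3]`;
#' initialization comes from the series endpoints and log-linearized
#' residuals. A flat series is returned as a degenerate fit with
#' `at_start == at_end` rather than an error.
#'
#' @param series Data frame with columns `time_h`, `atom_percent`; at least 3
#'   observations spanning `t = 0` to `t = window`.
#' @param window Incubation window in hours (default 48) over which
#'   [average_enrichment()] integrates.
#' @return Object of class `vs_equilibration_fit`: `at_start`, `at_end`, `b`,
#'   `window`, `average_atpct`, `degenerate`, `converged`, `residual_sd`, and
#'   the data used.
#' @export
#' @examples
#' tt <- c(0, 3, 6, 16, 48)
#' series <- tibble::tibble(time_h = tt,
#'   atom_percent = 16.1 + (0.0155 - 16.1) * exp(-0.12 * tt))
#' fit_equilibration(series)
fit_equilibration <- function(series, window = 48) {
  s <- tibble::as_tibble(series)
  if (!all(c("time_h", "atom_percent") %in% names(s))) {
    abort("series needs columns time_h and atom_percent.",
          class = "vs_schema_error")
  }
  s <- dplyr::arrange(s, .data$time_h)
  if (nrow(s) < 3) {
    abort("need at least 3 observations to fit the equilibration curve.",
          class = "vs_data_error")
  }
  if (min(s$time_h) > 0 || max(s$time_h) < window) {
    abort("series must include t = 0 and reach the incubation window.",
          class = "vs_data_error")
  }
  y <- s$atom_percent
  tt <- s$time_h

  if (diff(range(y)) < 1e-12 * max(abs(y), 1)) {
    # flat series: b unidentifiable
    fit <- new_equilibration_fit(y[1], y[1], NA_real_, window,
                                 degenerate = TRUE, converged = TRUE,
                                 residual_sd = 0, data = s)
    return(fit)
  }

  a0 <- y[which.min(tt)]
  a_inf0 <- y[which.max(tt)]
  # log-linearized initial slope: log|y - a_inf| ~ log|a0 - a_inf| - b t
  z <- abs(y - a_inf0)
  ok <- z > 1e-9 * abs(a0 - a_inf0)
  b0 <- if (sum(ok) >= 2) {
    max(1e-4, -unname(coef(lm(log(z[ok]) ~ tt[ok]))[2]))
  } else 0.1

  fit <- tryCatch(
    minpack.lm::nlsLM(
      atom_percent ~ at_end + (at_start - at_end) * exp(-b * time_h),
      data = s,
      start = list(at_start = a0, at_end = a_inf0, b = b0),
      lower = c(at_start = -Inf, at_end = -Inf, b = 1e-6),
      upper = c(at_start = Inf, at_end = Inf, b = 1e3),
      control = minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10,
                                           maxiter = 200)
    ),
    error = function(e) {
      abort(paste0("equilibration fit did not converge (initial guess: ",
                   "at_start=", signif(a0, 4), ", at_end=", signif(a_inf0, 4),
                   ", b=", signif(b0, 4), "): ", conditionMessage(e)),
            class = "vs_fit_error")
    }
  )
  cf <- coef(fit)
  new_equilibration_fit(unname(cf["at_start"]), unname(cf["at_end"]),
                        unname(cf["b"]), window,
                        degenerate = FALSE, converged = fit$convInfo$isConv %||% TRUE,
                        residual_sd = sd(resid(fit)), data = s)
}

new_equilibration_fit <- function(at_start, at_end, b, window, degenerate,
                                  converged, residual_sd, data) {
  obj <- structure(
    list(at_start = at_start, at_end = at_end, b = b, window = window,
         average_atpct = NA_real_, degenerate = degenerate,
         converged = converged, residual_sd = residual_sd, data = data),
    class = "vs_equilibration_fit"
  )
  obj$average_atpct <- average_enrichment(obj)
  obj
}

#' Time-averaged tracer enrichment over the incubation window
#'
#' Closed-form mean of the fitted exponential over `[0, W]`:
#' \deqn{\bar X = X_{end} + (X_{start} - X_{end})\,
#'   \frac{1 - e^{-bW}}{bW}.}
#' This average is the soil-water at% denominator used by the tracer
#' equations, accounting for the label arriving gradually rather than at full
#' strength from time zero.
#'
#' @param fit A `vs_equilibration_fit` (or a list with `at_start`, `at_end`,
#'   `b`, `window`).
#' @return Average at% over the window, a single number.
#' @export
average_enrichment <- function(fit) {
  w <- fit$window
  if (isTRUE(fit$degenerate) || is.na(fit$b)) {
    return(fit$at_end)
  }
  bw <- fit$b * w
  fit$at_end + (fit$at_start - fit$at_end) * (1 - exp(-bw)) / bw
}

#' Predict the fitted equilibration curve
#' @param object A `vs_equilibration_fit`.
#' @param time_h Times (hours) at which to evaluate the curve.
#' @param ... Unused.
#' @return Numeric vector of at% values.
#' @export
predict.vs_equilibration_fit <- function(object, time_h = NULL, ...) {
  time_h <- time_h %||% object$data$time_h
  if (isTRUE(object$degenerate) || is.na(object$b)) {
    return(rep(object$at_end, length(time_h)))
  }
  object$at_end + (object$at_start - object$at_end) * exp(-object$b * time_h)
}

#' @export
print.vs_equilibration_fit <- function(x, ...) {
  cat(sprintf(
    "<vs_equilibration_fit> at_start %.4f -> at_end %.4f at%%, b %.4g /h%s\n  mean over %g h: %.4f at%%\n",
    x$at_start, x$at_end, x$b,
    if (x$degenerate) " (degenerate: flat series)" else "",
    x$window, x$average_atpct))
  invisible(x)
}

#' @export
tidy.vs_equilibration_fit <- function(x, ...) {
  tibble::tibble(term = c("at_start", "at_end", "b"),
                 estimate = c(x$at_start, x$at_end, x$b))
}

#' @export
glance.vs_equilibration_fit <- function(x, ...) {
  tibble::tibble(average_atpct = x$average_atpct, window = x$window,
                 residual_sd = x$residual_sd, converged = x$converged,
                 degenerate = x$degenerate, n = nrow(x$data))
}

#' Fit equilibration curves per treatment and tabulate average enrichments
#'
#' Fits one curve per treatment x replicate series, then averages the
#' replicate fits' window means to a treatment-level soil-water at% (applied
#' downstream to all samples of that treatment). Treatments lacking a water
#' series in a phase (typically the recovery phase) fall back to the
#' drought-phase value of the matching non-drought climate: ambient and
#' drought use ambient's, future and future + drought use future's.
#'
#' @param water Water-series tibble from [read_water_table()]: columns
#'   `treatment, replicate, time_h, atom_percent`, optional `pool`
#'   (`"soil"` rows are used if present) and `tracer`.
#' @param window Incubation hours (default 48).
#' @return Tibble `tracer, treatment, phase, soil_water_atpct, n_fits` covering
#'   both phases.
#' @export
treatment_water_enrichment <- function(water, window = 48) {
  w <- tibble::as_tibble(water)
  if (!"tracer" %in% names(w)) w$tracer <- "2h"
  if ("pool" %in% names(w) && any(w$pool == "soil")) {
    w <- dplyr::filter(w, .data$pool == "soil")
  }
  fits <- w |>
    dplyr::group_by(.data$tracer, .data$treatment, .data$replicate) |>
    dplyr::group_modify(function(d, key) {
      f <- fit_equilibration(d, window = window)
      tibble::tibble(average_atpct = f$average_atpct)
    }) |>
    dplyr::ungroup()
  drought_phase <- fits |>
    dplyr::group_by(.data$tracer, .data$treatment) |>
    dplyr::summarise(soil_water_atpct = mean(.data$average_atpct),
                     n_fits = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(phase = "drought")
  fallback <- c(ambient = "ambient", drought = "ambient",
                future = "future", future_drought = "future")
  recovery <- drought_phase |>
    dplyr::select("tracer", "treatment", "soil_water_atpct", "n_fits") |>
    (\(d) {
      tibble::tibble(treatment = names(fallback),
                     source = unname(fallback)) |>
        dplyr::inner_join(d, by = c(source = "treatment"),
                          relationship = "many-to-many") |>
        dplyr::select(-"source")
    })() |>
    dplyr::mutate(phase = "recovery")
  dplyr::bind_rows(drought_phase, recovery) |>
    dplyr::select("tracer", "treatment", "phase", "soil_water_atpct", "n_fits") |>
    dplyr::arrange(.data$tracer, .data$phase, .data$treatment)
}
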