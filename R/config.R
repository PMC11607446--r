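#' Run configuration for a vapor-SIP analysis
#'
#' Bundles the physical constants and toggles shared by all pipeline stages.
#' Defaults follow common practice for soil heterotroph incubations: the water
#' hydrogen assimilation constant `a_w = 0.71` (the fraction of fatty-acid H
#' drawn from ambient water during biosynthesis, net of fractionation), a mean
#' DNA oxygen content of 31.21 % by mass, and the VSMOW isotope-ratio
#' constants for \eqn{^2}H and \eqn{^{18}}O.
#'
#' @param a_w Water hydrogen assimilation constant, dimensionless fraction in
#'   (0, 1]. Applied to fatty-acid (PLFA and NLFA) production only; DNA-based
#'   rates use no assimilation constant.
#' @param dna_oxygen_fraction Mean oxygen content of DNA, percent by mass.
#' @param r_vsmow_2h,r_vsmow_18o Heavy/light isotope ratios of the VSMOW
#'   reference (2H/1H and 18O/16O).
#' @param headspace_volume Default gas headspace volume in mL: a 27 mL vial
#'   minus the displacement of the inner soil vial. Per-sample values in a
#'   headspace table override this.
#' @param vial_displacement mL displaced by the inner vial and soil; only used
#'   to derive the default `headspace_volume` when that is `NULL`.
#' @param pressure Vial pressure in Pa used for the ideal-gas CO2 conversion.
#' @param internal_standard Marker name of the internal quantification
#'   standard; excluded from all community and group sums.
#' @param clamp_negative_enrichment If `TRUE` (default), tracer enrichments
#'   below natural abundance (IRMS noise around zero growth) yield a
#'   production of 0 and a `clamped` flag rather than negative production.
#' @param seed Optional integer seed recorded in the configuration and used
#'   by [vs_run_pipeline()] when simulation is involved.
#'
#' @return A list of class `vs_config`.
#' @export
#' @examples
#' cfg <- vs_config()
#' cfg$a_w
vs_config <- function(a_w = 0.71,
                      dna_oxygen_fraction = 31.21,
                      r_vsmow_2h = 0.00015576,
                      r_vsmow_18o = 0.0020052,
                      headspace_volume = NULL,
                      vial_displacement = 1.2,
                      pressure = 101325,
                      internal_standard = "19:0",
                      clamp_negative_enrichment = TRUE,
                      seed = NULL) {
  if (!is.numeric(a_w) || length(a_w) != 1 || a_w <= 0 || a_w > 1) {
    abort("`a_w` must be a single number in (0, 1].", class = "vs_config_error")
  }
  if (!is.numeric(dna_oxygen_fraction) || dna_oxygen_fraction <= 0 ||
      dna_oxygen_fraction >= 100) {
    abort("`dna_oxygen_fraction` must be a percentage in (0, 100).",
          class = "vs_config_error")
  }
  headspace_volume <- headspace_volume %||% (27 - vial_displacement)
  structure(
    list(
      a_w = a_w,
      dna_oxygen_fraction = dna_oxygen_fraction,
      r_vsmow_2h = r_vsmow_2h,
      r_vsmow_18o = r_vsmow_18o,
      headspace_volume = headspace_volume,
      pressure = pressure,
      internal_standard = internal_standard,
      clamp_negative_enrichment = clamp_negative_enrichment,
      seed = seed
    ),
    class = "vs_config"
  )
}

#' @export
print.vs_config <- function(x, ...) {
  cat("<vs_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-26s %s\n", nm, format(x[[nm]] %||% "<unset>")))
  }
  invisible(x)
}

# closed treatment / phase vocabularies used throughout
vs_treatments <- c("ambient", "drought", "future", "future_drought")
vs_phases <- c("drought", "recovery")

#' Treatment and phase levels
#'
#' The closed vocabularies for the climate treatments (ambient, drought,
#' future climate, future climate + drought) and sampling phases (peak
#' drought, recovery after rewetting) recognised by the validators.
#'
#' @return Character vector of levels.
#' @export
vs_treatment_levels <- function() vs_treatments

#' @rdname vs_treatment_levels
#' @export
vs_phase_levels <- function() vs_phases
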