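#' Fraction of a pool newly synthesised during the incubation
#'
#' The kernel shared by the fatty-acid and DNA tracer equations: excess heavy
#' isotope in the biomolecule over its natural abundance, divided by the
#' (assimilation-scaled) tracer enrichment of the soil water,
#' \deqn{f = \frac{at\%_{labelled} - at\%_{natural}}
#'              {a \cdot at\%_{soil\,water}}.}
#' For fatty acids `assimilation` is the water hydrogen assimilation constant
#' `a_w`; for DNA it is 1 (no assimilation constant is used).
#'
#' @param atpct_labelled,atpct_natural Heavy-isotope at% of the labelled and
#'   natural-abundance incubation.
#' @param soil_water_atpct Time-averaged soil-water tracer at% (> natural
#'   abundance).
#' @param assimilation Fraction of the biomolecule's element drawn from soil
#'   water, in (0, 1].
#' @param clamp If `TRUE`, negative excess enrichment (instrument noise at
#'   near-zero growth) yields 0 with `clamped = TRUE`.
#' @return Tibble `fraction_new, clamped`.
#' @export
tracer_fraction_new <- function(atpct_labelled, atpct_natural,
                                soil_water_atpct, assimilation = 1,
                                clamp = TRUE) {
  if (any(soil_water_atpct <= 0)) {
    abort("soil water enrichment must be positive.", class = "vs_domain_error")
  }
  if (any(assimilation <= 0 | assimilation > 1)) {
    abort("assimilation constant must lie in (0, 1].",
          class = "vs_domain_error")
  }
  f <- (atpct_labelled - atpct_natural) / (assimilation * soil_water_atpct)
  clamped <- f < 0
  if (clamp) f[clamped] <- 0
  tibble::tibble(fraction_new = f, clamped = clamped & clamp)
}
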