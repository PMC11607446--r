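#' Ground-truth parameters for a synthetic vapor-SIP incubation
#'
#' Defines the full study conditions of a simulated experiment: a montane
#' grassland soil sampled from four climate treatments (ambient, drought,
#' future climate, future climate + drought) at two phases (peak drought,
#' recovery after rewetting), n plots per treatment, incubated 48 h with
#' 2H-labelled water vapor (fatty acids) and 18O-labelled water vapor (DNA).
#'
#' Default effect sizes echo the qualitative findings the generator is meant
#' to emulate: drought roughly halves bacterial mass-specific growth while
#' fungal growth is unchanged, actinobacteria decline least among bacteria,
#' fungal NLFA (storage) synthesis jumps from ~22 % of PLFA synthesis to
#' several-fold during drought, and all groups return to ambient-like rates
#' during recovery. Instrument noise defaults to 4 per-mil on delta-2H (added
#' in delta space, where IRMS noise lives, then converted to at%).
#'
#' @param n_plots Plots per treatment (default 4).
#' @param biomass_c Microbial biomass C, ug C per g dry soil.
#' @param total_plfa_c Total PLFA carbon, ng C per g dry soil.
#' @param nlfa_pool_ratio NLFA pool size relative to the PLFA pool for
#'   markers present in the neutral fraction.
#' @param group_rates Tibble `phase, treatment, group, rate_per_day` of
#'   mass-specific PLFA production rates; `NULL` for the defaults.
#' @param nlfa_investment Tibble `phase, treatment, group, investment` of
#'   NLFA:PLFA production ratios; `NULL` for the defaults.
#' @param respiration Tibble `phase, treatment, respiration` in ng C
#'   g^-1 h^-1; `NULL` for the defaults.
#' @param water Tibble `tracer, treatment, at_start, at_end, b` of true
#'   equilibration parameters; `NULL` for the defaults.
#' @param marker_composition Tibble `marker, fraction_of_plfa_c, in_nlfa`;
#'   fractions must sum to 1.
#' @param a_w_true Water hydrogen assimilation constant used in generation.
#' @param noise List: `delta2h_sd` (per mil), `at18o_sd` (at%), `co2_sd`
#'   (ppm), `water_sd` (at%), `plot_sd` (lognormal sd of the plot-level rate
#'   multiplier). Set all to 0 for a noise-free dataset.
#' @param soil_dry_mass g dry soil per vial.
#' @param soil_water_mass,source_water_mass g water in the soil and source
#'   pools (for the mass-balance series).
#' @param incubation_time Hours.
#' @param total_dna ug DNA per g dry soil.
#' @param nat_ab Natural-abundance at% values: `plfa`, `nlfa`, `dna`,
#'   `water_2h`, `water_18o`.
#' @param co2_baseline Headspace CO2 at t0, ppm.
#' @return List of class `vs_truth`.
#' @export
vs_truth <- function(n_plots = 4,
                     biomass_c = 1000,
                     total_plfa_c = 30000,
                     nlfa_pool_ratio = 0.5,
                     group_rates = NULL,
                     nlfa_investment = NULL,
                     respiration = NULL,
                     water = NULL,
                     marker_composition = NULL,
                     a_w_true = 0.71,
                     noise = list(),
                     soil_dry_mass = 0.8,
                     soil_water_mass = 0.24,
                     source_water_mass = 0.5,
                     incubation_time = 48,
                     total_dna = 5,
                     nat_ab = list(plfa = 0.0136, nlfa = 0.014, dna = 0.203,
                                   water_2h = 0.0155, water_18o = 0.2),
                     co2_baseline = 420) {
  noise <- utils::modifyList(
    list(delta2h_sd = 4, at18o_sd = 5e-4, co2_sd = 5, water_sd = 0,
         plot_sd = 0.15),
    noise)

  group_rates <- group_rates %||% default_group_rates()
  nlfa_investment <- nlfa_investment %||% default_nlfa_investment()
  respiration <- respiration %||% default_respiration()
  water <- water %||% default_water_params(nat_ab)
  marker_composition <- marker_composition %||% default_marker_composition()

  if (abs(sum(marker_composition$fraction_of_plfa_c) - 1) > 1e-12) {
    abort("marker composition fractions must sum to 1.",
          class = "vs_truth_error")
  }
  if (any(group_rates$rate_per_day < 0) || any(respiration$respiration < 0)) {
    abort("rates must be non-negative.", class = "vs_truth_error")
  }
  structure(
    list(n_plots = n_plots, biomass_c = biomass_c,
         total_plfa_c = total_plfa_c, nlfa_pool_ratio = nlfa_pool_ratio,
         group_rates = group_rates, nlfa_investment = nlfa_investment,
         respiration = respiration, water = water,
         marker_composition = marker_composition, a_w_true = a_w_true,
         noise = noise, soil_dry_mass = soil_dry_mass,
         soil_water_mass = soil_water_mass,
         source_water_mass = source_water_mass,
         incubation_time = incubation_time, total_dna = total_dna,
         nat_ab = nat_ab, co2_baseline = co2_baseline),
    class = "vs_truth"
  )
}

expand_pt <- function(...) {
  tidyr::expand_grid(phase = vs_phases, treatment = vs_treatments, ...)
}

default_group_rates <- function() {
  groups <- vs_group_levels
  ambient_like <- c(fungi = 0.0105, amf = 0.010, gram_positive = 0.011,
                    gram_negative = 0.011, actinobacteria = 0.010,
                    general = 0.010)
  # drought multipliers at peak drought: bacteria ~halved, fungi unchanged,
  # actinobacteria least affected among bacteria
  mult_drought <- c(fungi = 1, amf = 1, gram_positive = 0.51,
                    gram_negative = 0.46, actinobacteria = 0.78,
                    general = 0.55)
  mult_future_drought <- c(fungi = 1, amf = 1, gram_positive = 0.47,
                           gram_negative = 0.51, actinobacteria = 0.56,
                           general = 0.55)
  expand_pt(group = groups) |>
    dplyr::mutate(rate_per_day = dplyr::case_when(
      phase == "recovery" ~ ambient_like[group],
      treatment == "drought" ~ ambient_like[group] * mult_drought[group],
      treatment == "future_drought" ~
        ambient_like[group] * mult_future_drought[group],
      TRUE ~ ambient_like[group]
    ) |> unname())
}

default_nlfa_investment <- function() {
  base <- c(fungi = 0.22, amf = 0.20, gram_negative = 0.010, general = 0.020)
  drought <- c(fungi = 2.28, amf = 0.60, gram_negative = 0.063,
               general = 0.050)
  future_drought <- c(fungi = 3.05, amf = 0.60, gram_negative = 0.055,
                      general = 0.050)
  expand_pt(group = names(base)) |>
    dplyr::mutate(investment = dplyr::case_when(
      phase == "recovery" ~ base[group],
      treatment == "drought" ~ drought[group],
      treatment == "future_drought" ~ future_drought[group],
      TRUE ~ base[group]
    ) |> unname())
}

default_respiration <- function() {
  expand_pt() |>
    dplyr::mutate(respiration = dplyr::case_when(
      phase == "drought" & treatment == "ambient" ~ 800,
      phase == "drought" & treatment == "drought" ~ 430,
      phase == "drought" & treatment == "future" ~ 850,
      phase == "drought" & treatment == "future_drought" ~ 470,
      phase == "recovery" & treatment %in% c("future", "future_drought") ~ 1300,
      TRUE ~ 800
    ))
}

default_water_params <- function(nat_ab) {
  dplyr::bind_rows(
    tibble::tibble(
      tracer = "2h", treatment = vs_treatments,
      at_start = nat_ab$water_2h,
      at_end = c(20.5, 16.0, 24.0, 19.6), b = 0.1),
    tibble::tibble(
      tracer = "18o", treatment = vs_treatments,
      at_start = nat_ab$water_18o,
      at_end = c(22.1, 20.6, 23.4, 21.7), b = 0.25)
  )
}

default_marker_composition <- function() {
  tibble::tribble(
    ~marker,      ~fraction_of_plfa_c, ~in_nlfa,
    "18:1w9c",    0.09,  TRUE,
    "18:2w6,9",   0.06,  TRUE,
    "16:1w5",     0.04,  TRUE,
    "10Me16:0",   0.04,  FALSE,
    "10Me17:0",   0.02,  FALSE,
    "10Me18:0",   0.02,  FALSE,
    "i15:0",      0.08,  FALSE,
    "a15:0",      0.06,  FALSE,
    "i16:0",      0.04,  FALSE,
    "i17:0",      0.03,  FALSE,
    "a17:0",      0.03,  FALSE,
    "16:1w7",     0.08,  TRUE,
    "cy17:0",     0.04,  FALSE,
    "cy19:0",     0.06,  FALSE,
    "18:1w9t",    0.04,  TRUE,
    "16:0",       0.16,  TRUE,
    "17:0",       0.03,  FALSE,
    "18:0",       0.08,  TRUE
  )
}

#' True time-averaged soil-water enrichment per tracer and treatment
#'
#' Closed-form window mean of the truth's equilibration curves; during the
#' recovery phase treatments reuse the matching non-drought climate's value
#' (no water series is collected then).
#'
#' @param truth A [vs_truth()].
#' @return Tibble `tracer, treatment, phase, soil_water_atpct`.
#' @export
truth_water_average <- function(truth) {
  w <- truth$water |>
    dplyr::rowwise() |>
    dplyr::mutate(soil_water_atpct = average_enrichment(
      list(at_start = .data$at_start, at_end = .data$at_end, b = .data$b,
           window = truth$incubation_time, degenerate = FALSE))) |>
    dplyr::ungroup() |>
    dplyr::select("tracer", "treatment", "soil_water_atpct")
  fallback <- c(ambient = "ambient", drought = "ambient",
                future = "future", future_drought = "future")
  dplyr::bind_rows(
    dplyr::mutate(w, phase = "drought"),
    tibble::tibble(treatment = names(fallback), source = unname(fallback)) |>
      dplyr::inner_join(dplyr::rename(w, source = "treatment"),
                        by = "source", relationship = "many-to-many") |>
      dplyr::select(-"source") |>
      dplyr::mutate(phase = "recovery")
  )
}

#' Simulate the water-equilibration time series
#'
#' Exact exponential soil-water trajectories at the canonical sampling times
#' (0, 3, 6, 16, 48 h) for each tracer, treatment and replicate, plus the
#' corresponding source-water series obtained by exact two-pool mass balance
#' (label conserved pre-noise). Gaussian at% noise (`noise$water_sd`) is added
#' after the mass balance.
#'
#' @param truth A [vs_truth()].
#' @param seed Integer seed.
#' @param n_replicates Series per treatment (default 2).
#' @param times Sampling times in hours.
#' @return Tibble `tracer, treatment, replicate, pool, time_h, atom_percent`.
#' @export
simulate_water_series <- function(truth, seed, n_replicates = 2,
                                  times = c(0, 3, 6, 16, 48)) {
  set.seed(seed)
  grid <- tidyr::expand_grid(truth$water,
                             replicate = seq_len(n_replicates),
                             time_h = times)
  soil <- grid |>
    dplyr::mutate(
      pool = "soil",
      atom_percent = .data$at_end +
        (.data$at_start - .data$at_end) * exp(-.data$b * .data$time_h))
  # two-pool conservation: source loses what soil gains, scaled by masses
  src0 <- 60  # at% of the added labelled water at t = 0
  source <- soil |>
    dplyr::mutate(
      pool = "source",
      atom_percent = src0 - truth$soil_water_mass / truth$source_water_mass *
        (.data$atom_percent - .data$at_start))
  out <- dplyr::bind_rows(soil, source) |>
    dplyr::mutate(atom_percent = .data$atom_percent +
                    stats::rnorm(dplyr::n(), 0, truth$noise$water_sd)) |>
    dplyr::select("tracer", "treatment", "replicate", "pool", "time_h",
                  "atom_percent") |>
    dplyr::arrange(.data$tracer, .data$treatment, .data$replicate,
                   .data$pool, .data$time_h)
  out
}

# sample frame shared by the generators: one row per plot x phase x assay
truth_sample_frame <- function(truth) {
  plots <- tidyr::expand_grid(treatment = vs_treatments,
                              plot = seq_len(truth$n_plots)) |>
    dplyr::mutate(plot_id = sprintf("plot%02d", dplyr::row_number()))
  tidyr::expand_grid(plots, phase = vs_phases,
                     assay = c("2h", "18o")) |>
    dplyr::mutate(sample_id = paste(.data$plot_id, .data$treatment,
                                    .data$phase, .data$assay, sep = "_"))
}

# lognormal plot-level rate multiplier with unit mean
plot_multipliers <- function(truth, plot_ids, seed) {
  set.seed(seed + 1L)
  sdlog <- truth$noise$plot_sd
  ids <- sort(unique(plot_ids))
  mult <- if (sdlog > 0) {
    exp(stats::rnorm(length(ids), -sdlog^2 / 2, sdlog))
  } else rep(1, length(ids))
  setNames(mult, ids)
}

#' Simulate sample metadata
#'
#' @param truth A [vs_truth()].
#' @return Tibble with one row per incubated sample (plot x phase x assay):
#'   `sample_id, plot_id, treatment, phase, assay, soil_dry_mass,
#'   incubation_time, temperature, microbial_biomass_c`.
#' @export
simulate_metadata <- function(truth) {
  truth_sample_frame(truth) |>
    dplyr::mutate(
      soil_dry_mass = truth$soil_dry_mass,
      incubation_time = truth$incubation_time,
      temperature = ifelse(.data$treatment %in% c("future", "future_drought"),
                           23, 20),
      microbial_biomass_c = truth$biomass_c) |>
    dplyr::select("sample_id", "plot_id", "treatment", "phase", "assay",
                  "soil_dry_mass", "incubation_time", "temperature",
                  "microbial_biomass_c")
}

#' Simulate the paired fatty-acid table
#'
#' Inverts the fatty-acid tracer equation: for each 2H sample and marker the
#' newly produced fraction is the group's mass-specific rate times the
#' incubation time (times a plot-level multiplier), and
#' `at%_labelled = at%_natural + f * a_w * mean soil-water at%`. NLFA records
#' are scaled by the group's storage-investment ratio. Delta-space Gaussian
#' noise (`noise$delta2h_sd`, per mil) is added to labelled and natural
#' values independently, then converted back to at%.
#'
#' @param truth A [vs_truth()].
#' @param seed Integer seed.
#' @param meta Metadata from [simulate_metadata()] (regenerated if `NULL`).
#' @return Tibble `sample_id, marker, fraction, atpct_labelled,
#'   atpct_natural, fa_c, units`.
#' @export
simulate_fame_table <- function(truth, seed, meta = NULL) {
  meta <- meta %||% simulate_metadata(truth)
  mult <- plot_multipliers(truth, meta$plot_id, seed)
  water <- truth_water_average(truth) |>
    dplyr::filter(.data$tracer == "2h")
  comp <- truth$marker_composition |>
    dplyr::mutate(group = assign_markers(.data$marker, quiet = TRUE)$group)

  base <- meta |>
    dplyr::filter(.data$assay == "2h") |>
    dplyr::left_join(water, by = c("treatment", "phase")) |>
    tidyr::expand_grid(comp) |>
    dplyr::left_join(truth$group_rates,
                     by = c("phase", "treatment", "group"))

  plfa <- base |>
    dplyr::mutate(
      fraction = "plfa",
      fa_c = .data$fraction_of_plfa_c * truth$total_plfa_c,
      f_new = .data$rate_per_day / 24 * truth$incubation_time *
        unname(mult[.data$plot_id]))

  nlfa <- base |>
    dplyr::filter(.data$in_nlfa) |>
    dplyr::left_join(truth$nlfa_investment,
                     by = c("phase", "treatment", "group")) |>
    dplyr::mutate(
      fraction = "nlfa",
      fa_c = .data$fraction_of_plfa_c * truth$total_plfa_c *
        truth$nlfa_pool_ratio,
      # investment is NLFA C produced : PLFA C produced for the same marker
      f_new = .data$rate_per_day / 24 * truth$incubation_time *
        unname(mult[.data$plot_id]) * .data$investment / truth$nlfa_pool_ratio)

  out <- dplyr::bind_rows(plfa, nlfa)
  if (any(out$f_new >= 1)) {
    abort("truth implies a pool turning over more than once in the incubation.",
          class = "vs_truth_error")
  }
  nat_base <- ifelse(out$fraction == "plfa", truth$nat_ab$plfa,
                     truth$nat_ab$nlfa)
  lab_true <- nat_base + out$f_new * truth$a_w_true * out$soil_water_atpct

  set.seed(seed + 2L)
  r2h <- 0.00015576
  jitter_delta <- function(atpct) {
    if (truth$noise$delta2h_sd == 0) return(atpct)
    d <- atom_percent_to_delta(atpct, r2h) +
      stats::rnorm(length(atpct), 0, truth$noise$delta2h_sd)
    delta_to_atom_percent(d, r2h)
  }
  out$atpct_labelled <- jitter_delta(lab_true)
  out$atpct_natural <- jitter_delta(nat_base)
  out |>
    dplyr::mutate(units = "atom_percent") |>
    dplyr::select("sample_id", "marker", "fraction", "atpct_labelled",
                  "atpct_natural", "fa_c", "units") |>
    dplyr::arrange(.data$sample_id, .data$fraction, .data$marker)
}

# PLFA-C-weighted community mass-specific rate implied by the group rates
truth_community_rate <- function(truth) {
  comp <- truth$marker_composition |>
    dplyr::mutate(group = assign_markers(.data$marker, quiet = TRUE)$group)
  truth$group_rates |>
    dplyr::inner_join(comp, by = "group", relationship = "many-to-many") |>
    dplyr::group_by(.data$phase, .data$treatment) |>
    dplyr::summarise(
      community_rate_per_day = sum(.data$rate_per_day *
                                     .data$fraction_of_plfa_c),
      .groups = "drop")
}

#' Simulate the DNA table
#'
#' Sets each 18O sample's labelled DNA at% so that the DNA tracer equations
#' recover the same community mass-specific growth rate as the lipid truth
#' (no assimilation constant on the DNA path); the extract oxygen content is
#' the DNA oxygen fraction times total DNA. Gaussian at% noise
#' (`noise$at18o_sd`) is added to labelled and natural values.
#'
#' @param truth A [vs_truth()].
#' @param seed Integer seed.
#' @param meta Metadata from [simulate_metadata()] (regenerated if `NULL`).
#' @param dna_oxygen_fraction Percent oxygen in DNA used in generation.
#' @return Tibble `sample_id, o_dna_extract, atpct_labelled, atpct_natural,
#'   total_dna`.
#' @export
simulate_dna_table <- function(truth, seed, meta = NULL,
                               dna_oxygen_fraction = 31.21) {
  meta <- meta %||% simulate_metadata(truth)
  mult <- plot_multipliers(truth, meta$plot_id, seed)
  water <- truth_water_average(truth) |>
    dplyr::filter(.data$tracer == "18o")
  out <- meta |>
    dplyr::filter(.data$assay == "18o") |>
    dplyr::left_join(water, by = c("treatment", "phase")) |>
    dplyr::left_join(truth_community_rate(truth),
                     by = c("phase", "treatment")) |>
    dplyr::mutate(
      f_new = .data$community_rate_per_day / 24 * truth$incubation_time *
        unname(mult[.data$plot_id]),
      total_dna = truth$total_dna,
      o_dna_extract = dna_oxygen_fraction / 100 * .data$total_dna,
      atpct_natural = truth$nat_ab$dna,
      atpct_labelled = .data$atpct_natural +
        .data$f_new * .data$soil_water_atpct)
  set.seed(seed + 3L)
  if (truth$noise$at18o_sd > 0) {
    out$atpct_labelled <- out$atpct_labelled +
      stats::rnorm(nrow(out), 0, truth$noise$at18o_sd)
    out$atpct_natural <- out$atpct_natural +
      stats::rnorm(nrow(out), 0, truth$noise$at18o_sd)
  }
  dplyr::select(out, "sample_id", "o_dna_extract", "atpct_labelled",
                "atpct_natural", "total_dna")
}

#' Simulate headspace CO2 readings
#'
#' Inverts the ideal-gas respiration conversion: the ppm rise over the
#' incubation consistent with the treatment's true respiration rate (times
#' the plot multiplier), at the sample's temperature and vial volume. Both a
#' labelled and a natural-abundance vial are generated per sample (the
#' natural one backs the label-toxicity paired t-test) with independent ppm
#' noise (`noise$co2_sd`).
#'
#' @param truth A [vs_truth()].
#' @param seed Integer seed.
#' @param meta Metadata from [simulate_metadata()] (regenerated if `NULL`).
#' @param headspace_volume Vial headspace volume, mL.
#' @param pressure Vial pressure, Pa.
#' @return Tibble `sample_id, labelling, co2_t0, co2_t1, headspace_volume,
#'   elapsed`.
#' @export
simulate_headspace <- function(truth, seed, meta = NULL,
                               headspace_volume = 25.8, pressure = 101325) {
  meta <- meta %||% simulate_metadata(truth)
  mult <- plot_multipliers(truth, meta$plot_id, seed)
  gas_const <- 8.31446261815324
  out <- meta |>
    dplyr::left_join(truth$respiration, by = c("phase", "treatment")) |>
    tidyr::expand_grid(labelling = c("labelled", "natural")) |>
    dplyr::mutate(
      resp = .data$respiration * unname(mult[.data$plot_id]),
      mol_co2 = .data$resp * .data$soil_dry_mass * .data$incubation_time /
        12.011e9,
      dppm = .data$mol_co2 * gas_const * (.data$temperature + 273.15) /
        (pressure * headspace_volume * 1e-6) * 1e6,
      co2_t0 = truth$co2_baseline,
      co2_t1 = .data$co2_t0 + .data$dppm,
      headspace_volume = headspace_volume,
      elapsed = .data$incubation_time)
  set.seed(seed + 4L)
  if (truth$noise$co2_sd > 0) {
    out$co2_t0 <- out$co2_t0 + stats::rnorm(nrow(out), 0, truth$noise$co2_sd)
    out$co2_t1 <- out$co2_t1 + stats::rnorm(nrow(out), 0, truth$noise$co2_sd)
  }
  dplyr::select(out, "sample_id", "labelling", "co2_t0", "co2_t1",
                "headspace_volume", "elapsed")
}

#' Simulate a complete vapor-SIP incubation dataset
#'
#' Forward-simulates all five input tables (metadata, paired fatty-acid
#' records, water-equilibration series, DNA records, headspace CO2) plus a
#' per-sample expectation table computed analytically from the truth, so
#' every pipeline stage can be validated by parameter recovery.
#'
#' @param truth A [vs_truth()]; defaults to the standard study conditions.
#' @param seed Integer seed (mandatory; same seed, same dataset).
#' @return List of class `vs_dataset`: `meta`, `fame`, `water`, `dna`,
#'   `headspace`, `expected`, `truth`, `seed`.
#' @export
#' @examples
#' ds <- vs_simulate_dataset(vs_truth(), seed = 1)
#' names(ds)
vs_simulate_dataset <- function(truth = vs_truth(), seed) {
  if (missing(seed) || !is.numeric(seed)) {
    abort("an integer seed is required.", class = "vs_truth_error")
  }
  seed <- as.integer(seed)
  meta <- simulate_metadata(truth)
  mult <- plot_multipliers(truth, meta$plot_id, seed)
  water_avg <- truth_water_average(truth)

  expected <- meta |>
    dplyr::left_join(truth_community_rate(truth),
                     by = c("phase", "treatment")) |>
    dplyr::left_join(truth$respiration, by = c("phase", "treatment")) |>
    dplyr::left_join(
      dplyr::rename(water_avg, assay = "tracer"),
      by = c("assay", "treatment", "phase")) |>
    dplyr::mutate(
      plot_multiplier = unname(mult[.data$plot_id]),
      ms_growth_per_day = .data$community_rate_per_day *
        .data$plot_multiplier,
      growth = .data$ms_growth_per_day / 24 * .data$microbial_biomass_c *
        1000,
      respiration = .data$respiration * .data$plot_multiplier,
      cue = .data$growth / (.data$growth + .data$respiration),
      turnover_days = 1 / .data$ms_growth_per_day) |>
    dplyr::select("sample_id", "plot_id", "treatment", "phase", "assay",
                  "plot_multiplier", "soil_water_atpct", "ms_growth_per_day",
                  "growth", "respiration", "cue", "turnover_days")

  structure(
    list(meta = meta,
         fame = simulate_fame_table(truth, seed, meta),
         water = simulate_water_series(truth, seed),
         dna = simulate_dna_table(truth, seed, meta),
         headspace = simulate_headspace(truth, seed, meta),
         expected = expected,
         truth = truth,
         seed = seed),
    class = "vs_dataset"
  )
}

#' @export
print.vs_dataset <- function(x, ...) {
  cat(sprintf(
    "<vs_dataset> seed %d: %d samples, %d fatty-acid records, %d water observations, %d DNA samples\n",
    x$seed, nrow(x$meta), nrow(x$fame), nrow(x$water), nrow(x$dna)))
  invisible(x)
}
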