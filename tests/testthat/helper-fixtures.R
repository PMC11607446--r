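# noise-free study conditions: the generator/estimator inverse-pair baseline
truth_noise_free <- function(...) {
  vs_truth(noise = list(delta2h_sd = 0, at18o_sd = 0, co2_sd = 0,
                        water_sd = 0, plot_sd = 0), ...)
}

# delta-noise-only conditions (IRMS noise on 2H, everything else exact)
truth_delta_noise <- function(sd = 4, ...) {
  vs_truth(noise = list(delta2h_sd = sd, at18o_sd = 0, co2_sd = 0,
                        water_sd = 0, plot_sd = 0), ...)
}

default_rates_fixture <- function() vs_truth()$group_rates

# one synthetic sample's paired fatty-acid records built by hand
tiny_fame <- function(sample_id = "s1") {
  tibble::tribble(
    ~sample_id, ~marker,     ~fraction, ~atpct_labelled, ~atpct_natural, ~fa_c,
    sample_id,  "18:2w6,9",  "plfa",    0.207,           0.0136,         100,
    sample_id,  "i15:0",     "plfa",    0.207,           0.0136,         200,
    sample_id,  "16:1w7",    "plfa",    0.110,           0.0136,         300,
    sample_id,  "16:0",      "plfa",    0.050,           0.0136,         400
  )
}

tiny_meta <- function(sample_id = "s1") {
  tibble::tibble(sample_id = sample_id, plot_id = "p1",
                 treatment = "ambient", phase = "drought",
                 soil_dry_mass = 0.8, incubation_time = 48,
                 temperature = 20, microbial_biomass_c = 1000)
}

write_fixture_csv <- function(df, name) {
  path <- file.path(withr::local_tempdir(.local_envir = parent.frame()), name)
  readr::write_csv(df, path)
  path
}
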