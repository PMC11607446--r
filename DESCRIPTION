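Package: vaporsip
Title: Vapor-Equilibration Stable Isotope Probing of Soil Microbial Growth
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calculates soil microbial growth, storage-compound synthesis,
    carbon use efficiency and biomass turnover from water-vapor
    stable-isotope-probing incubations. Converts raw GC-IRMS delta values to
    atom percent on the VSMOW scale with drift-corrected bracketing-standard
    calibration, fits the exponential equilibration of isotopically labelled
    water vapor with soil water and integrates it to a time-averaged tracer
    enrichment, and propagates 2H enrichment of phospholipid and neutral-lipid
    fatty acids (PLFA/NLFA) and 18O enrichment of DNA into per-marker,
    per-group and community-level production rates, mass-specific growth,
    fungal storage investment, CUE and turnover times. Includes a forward
    simulator of complete vapor-SIP incubation datasets with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
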