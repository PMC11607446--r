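# --- shared reading helpers -------------------------------------------------

# canonical lower_snake_case headers with a tolerant alias map
vs_alias_map <- c(
  "sampleid" = "sample_id", "sample" = "sample_id", "id" = "sample_id",
  "plot" = "plot_id", "plotid" = "plot_id",
  "compound" = "marker", "fame" = "marker", "fattyacid" = "marker",
  "atlabelled" = "atpct_labelled", "atpctlabelled" = "atpct_labelled",
  "atompercentlabelled" = "atpct_labelled",
  "atnatural" = "atpct_natural", "atpctnatural" = "atpct_natural",
  "atompercentnatural" = "atpct_natural",
  "deltalabelled" = "delta_labelled", "deltanatural" = "delta_natural",
  "fac" = "fa_c", "carbon" = "fa_c",
  "timeh" = "time_h", "time" = "time_h", "hours" = "time_h",
  "atompercent" = "atom_percent", "atpct" = "atom_percent",
  "at" = "atom_percent",
  "odnaextract" = "o_dna_extract", "odna" = "o_dna_extract",
  "totaldna" = "total_dna",
  "co2t0" = "co2_t0", "co2t1" = "co2_t1", "co2t48" = "co2_t1",
  "headspacevolume" = "headspace_volume", "volume" = "headspace_volume",
  "soildrymass" = "soil_dry_mass", "drymass" = "soil_dry_mass",
  "incubationtime" = "incubation_time",
  "microbialbiomassc" = "microbial_biomass_c", "biomassc" = "microbial_biomass_c",
  "unit" = "units"
)

canonical_headers <- function(nms) {
  key <- gsub("[^a-z0-9]", "", tolower(nms))
  canon <- gsub("[^a-z0-9_]", "", tolower(gsub("[ .-]+", "_", nms)))
  hit <- vs_alias_map[key]
  ifelse(is.na(hit), canon, hit)
}

vs_read_table <- function(path, required, numeric_cols = character(),
                          what = "input") {
  if (!file.exists(path)) {
    abort(paste0(what, " file not found: ", path), class = "vs_io_error")
  }
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = "c"))
  names(raw) <- canonical_headers(names(raw))
  miss <- setdiff(required, names(raw))
  if (length(miss)) {
    abort(paste0(what, " table `", basename(path),
                 "` is missing required column(s): ",
                 paste(miss, collapse = ", ")), class = "vs_schema_error")
  }
  for (col in intersect(numeric_cols, names(raw))) {
    val <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(val) & !is.na(raw[[col]]) & nzchar(raw[[col]]))
    if (length(bad)) {
      abort(paste0(what, " table `", basename(path), "`, column `", col,
                   "`: unparseable numeric value at data row(s) ",
                   paste(head(bad, 5), collapse = ", ")),
            class = "vs_parse_error")
    }
    raw[[col]] <- val
  }
  raw
}

# --- table readers ----------------------------------------------------------

#' Read and validate a sample metadata table
#'
#' @param path CSV with columns `sample_id, plot_id, treatment, phase` and
#'   the numeric columns `soil_dry_mass` (g), `incubation_time` (h),
#'   `temperature` (deg C), `microbial_biomass_c` (ug C / g dry soil).
#'   Optional `soil_water_content` (g water per g fresh soil) converts a
#'   `soil_fresh_mass` column to dry mass at read time.
#' @return Validated tibble.
#' @export
read_meta_table <- function(path) {
  m <- vs_read_table(
    path,
    required = c("sample_id", "plot_id", "treatment", "phase"),
    numeric_cols = c("soil_dry_mass", "soil_fresh_mass", "soil_water_content",
                     "incubation_time", "temperature", "microbial_biomass_c"),
    what = "metadata")
  if (!"soil_dry_mass" %in% names(m)) {
    if (all(c("soil_fresh_mass", "soil_water_content") %in% names(m))) {
      m$soil_dry_mass <- m$soil_fresh_mass * (1 - m$soil_water_content)
    } else {
      abort("metadata needs soil_dry_mass, or soil_fresh_mass plus soil_water_content.",
            class = "vs_schema_error")
    }
  }
  if (!"incubation_time" %in% names(m)) m$incubation_time <- 48
  m$treatment <- tolower(gsub("[ +]+", "_", trimws(m$treatment)))
  m$phase <- tolower(trimws(m$phase))
  bad_t <- setdiff(unique(m$treatment), vs_treatments)
  if (length(bad_t)) {
    abort(paste0("unknown treatment label(s): ", paste(bad_t, collapse = ", ")),
          class = "vs_schema_error")
  }
  bad_p <- setdiff(unique(m$phase), vs_phases)
  if (length(bad_p)) {
    abort(paste0("unknown phase label(s): ", paste(bad_p, collapse = ", ")),
          class = "vs_schema_error")
  }
  if (any(m$soil_dry_mass <= 0) || any(m$incubation_time <= 0)) {
    abort("soil_dry_mass and incubation_time must be positive.",
          class = "vs_domain_error")
  }
  if (anyDuplicated(m$sample_id)) {
    abort("duplicate sample_id in metadata.", class = "vs_schema_error")
  }
  m
}

#' Read and validate a fatty-acid table
#'
#' Accepts either atom-percent columns (`atpct_labelled, atpct_natural`) or
#' per-mil columns (`delta_labelled, delta_natural`, converted to at% on the
#' VSMOW 2H scale at read time), as declared by a `units` column
#' (`"atom_percent"` or `"delta_permil"`) present in the file. Lipid
#' fractions must be `plfa` or `nlfa` (case-insensitive). Rows of the
#' internal standard are dropped with a notice: the standard quantifies
#' carbon but carries no growth signal.
#'
#' @param path CSV path.
#' @param config A [vs_config()] (VSMOW constant, internal standard name).
#' @param quiet Suppress notices.
#' @return Tibble `sample_id, marker, fraction, atpct_labelled,
#'   atpct_natural, fa_c, units` (units always `atom_percent` on return).
#' @export
read_fame_table <- function(path, config = vs_config(), quiet = FALSE) {
  f <- vs_read_table(
    path,
    required = c("sample_id", "marker", "fraction"),
    numeric_cols = c("atpct_labelled", "atpct_natural", "delta_labelled",
                     "delta_natural", "fa_c"),
    what = "fatty-acid")
  f$fraction <- tolower(trimws(f$fraction))
  bad <- setdiff(unique(f$fraction), c("plfa", "nlfa"))
  if (length(bad)) {
    abort(paste0("unknown lipid fraction label(s): ",
                 paste(bad, collapse = ", "), " (expected plfa or nlfa)"),
          class = "vs_schema_error")
  }
  has_at <- all(c("atpct_labelled", "atpct_natural") %in% names(f))
  has_delta <- all(c("delta_labelled", "delta_natural") %in% names(f))
  if (!has_at && !has_delta) {
    abort("fatty-acid table needs atpct_labelled/atpct_natural or delta_labelled/delta_natural.",
          class = "vs_schema_error")
  }
  units <- if ("units" %in% names(f)) unique(tolower(f$units)) else
    if (has_at) "atom_percent" else "delta_permil"
  if (length(units) != 1 || !units %in% c("atom_percent", "delta_permil")) {
    abort("units column must be uniformly 'atom_percent' or 'delta_permil'.",
          class = "vs_schema_error")
  }
  if (units == "delta_permil") {
    if (!has_delta) {
      abort("units say delta_permil but no delta columns present.",
            class = "vs_schema_error")
    }
    f$atpct_labelled <- delta_to_atom_percent(f$delta_labelled,
                                              config$r_vsmow_2h)
    f$atpct_natural <- delta_to_atom_percent(f$delta_natural,
                                             config$r_vsmow_2h)
  }
  if (!"fa_c" %in% names(f)) {
    abort("fatty-acid table is missing required column(s): fa_c (quantify peak areas with quantify_fa_carbon() first).",
          class = "vs_schema_error")
  }
  is_key <- normalize_marker(config$internal_standard)
  is_rows <- normalize_marker(f$marker) == is_key
  if (any(is_rows)) {
    if (!quiet) {
      inform(paste0("dropping ", sum(is_rows), " internal-standard (",
                    config$internal_standard, ") row(s)."))
    }
    f <- f[!is_rows, ]
  }
  if (any(f$fa_c < 0, na.rm = TRUE)) {
    abort("fa_c must be non-negative.", class = "vs_domain_error")
  }
  at_cols <- c(f$atpct_labelled, f$atpct_natural)
  if (any(at_cols <= 0 | at_cols >= 100, na.rm = TRUE)) {
    abort("atom percent values must lie strictly between 0 and 100.",
          class = "vs_domain_error")
  }
  dplyr::mutate(f, units = "atom_percent") |>
    dplyr::select("sample_id", "marker", "fraction", "atpct_labelled",
                  "atpct_natural", "fa_c", "units")
}

#' Read and validate a water-equilibration series table
#'
#' @param path CSV with columns `treatment, replicate, time_h, atom_percent`
#'   and optionally `pool` (`source`/`soil`) and `tracer` (`2h`/`18o`).
#' @return Validated tibble.
#' @export
read_water_table <- function(path) {
  w <- vs_read_table(
    path,
    required = c("treatment", "replicate", "time_h", "atom_percent"),
    numeric_cols = c("time_h", "atom_percent"),
    what = "water-series")
  w$treatment <- tolower(gsub("[ +]+", "_", trimws(w$treatment)))
  if ("tracer" %in% names(w)) w$tracer <- tolower(w$tracer)
  if ("pool" %in% names(w)) {
    w$pool <- tolower(w$pool)
    bad <- setdiff(unique(w$pool), c("source", "soil"))
    if (length(bad)) {
      abort(paste0("unknown pool label(s): ", paste(bad, collapse = ", ")),
            class = "vs_schema_error")
    }
  }
  if (any(w$time_h < 0)) {
    abort("times must be non-negative.", class = "vs_domain_error")
  }
  if (any(w$atom_percent <= 0 | w$atom_percent >= 100)) {
    abort("atom percent values must lie strictly between 0 and 100.",
          class = "vs_domain_error")
  }
  w
}

#' Read and validate a DNA table
#'
#' @param path CSV with columns `sample_id, o_dna_extract, atpct_labelled,
#'   atpct_natural, total_dna` (all per g dry soil).
#' @return Validated tibble.
#' @export
read_dna_table <- function(path) {
  d <- vs_read_table(
    path,
    required = c("sample_id", "o_dna_extract", "atpct_labelled",
                 "atpct_natural", "total_dna"),
    numeric_cols = c("o_dna_extract", "atpct_labelled", "atpct_natural",
                     "total_dna", "soil_water_atpct"),
    what = "DNA")
  if (any(d$o_dna_extract > d$total_dna)) {
    abort("o_dna_extract cannot exceed total_dna (oxygen is a mass fraction of DNA).",
          class = "vs_domain_error")
  }
  at_cols <- c(d$atpct_labelled, d$atpct_natural)
  if (any(at_cols <= 0 | at_cols >= 100)) {
    abort("atom percent values must lie strictly between 0 and 100.",
          class = "vs_domain_error")
  }
  d
}

#' Read and validate a headspace CO2 table
#'
#' @param path CSV with columns `sample_id, co2_t0, co2_t1` (ppm), optional
#'   `labelling` (`labelled`/`natural`), `headspace_volume` (mL), `elapsed`
#'   (h).
#' @return Validated tibble.
#' @export
read_headspace_table <- function(path) {
  h <- vs_read_table(
    path,
    required = c("sample_id", "co2_t0", "co2_t1"),
    numeric_cols = c("co2_t0", "co2_t1", "headspace_volume", "elapsed",
                     "pressure"),
    what = "headspace")
  if (any(h$co2_t0 < 0 | h$co2_t1 < 0)) {
    abort("CO2 concentrations must be non-negative.",
          class = "vs_domain_error")
  }
  if ("labelling" %in% names(h)) h$labelling <- tolower(h$labelling)
  h
}

# --- writing ----------------------------------------------------------------

#' Write result tables to a directory
#'
#' Writes each table of a pipeline result (or any named list of data frames)
#' as an RFC-4180 CSV with full numeric precision, so re-reading reproduces
#' the values exactly.
#'
#' @param results Named list of data frames (e.g. from [vs_run_pipeline()]);
#'   non-data-frame elements are skipped.
#' @param path Output directory (created if needed).
#' @return Tibble manifest: `table, file, rows`.
#' @export
write_results <- function(results, path) {
  tabs <- purrr::keep(results, is.data.frame)
  if (!length(tabs)) {
    abort("no result tables to write.", class = "vs_io_error")
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) {
    abort(paste0("cannot create output directory: ", path),
          class = "vs_io_error")
  }
  manifest <- purrr::imap_dfr(tabs, function(tab, nm) {
    file <- file.path(path, paste0(nm, ".csv"))
    readr::write_csv(tab, file, progress = FALSE)
    tibble::tibble(table = nm, file = file, rows = nrow(tab))
  })
  manifest
}
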