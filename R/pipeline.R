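#' Run the full vapor-SIP analysis pipeline
#'
#' Executes every stage on an in-memory dataset: water-equilibration fits and
#' treatment-level average enrichments, fatty-acid tracer fluxes, community
#' and group growth rates, storage-investment percentages, DNA tracer fluxes,
#' respiration, per-sample physiology for both tracers, and the treatment
#' summaries. Stages whose inputs are absent are skipped (a DNA-only dataset
#' yields DNA outputs only). Deterministic: the same inputs give identical
#' outputs.
#'
#' @param data A `vs_dataset` from [vs_simulate_dataset()], or a named list
#'   with elements `meta`, `water`, and any of `fame`, `dna`, `headspace`
#'   (validated tibbles as returned by the `read_*_table()` readers).
#' @param config A [vs_config()].
#' @param registry Marker registry from [vs_registry()].
#' @param quiet Suppress stage logging.
#' @return A named list of class `vs_results` holding tidy tibbles:
#'   `water_enrichment`, `fame_fluxes`, `lipid_community`, `group_rates`,
#'   `fungi_bacteria`, `storage_pct`, `dna_growth`, `respiration`,
#'   `physiology`, `contrast_ms_growth`, `contrast_cue`,
#'   `contrast_fungal_storage`, `turnover`, `label_toxicity`.
#' @export
#' @examples
#' ds <- vs_simulate_dataset(vs_truth(), seed = 42)
#' res <- vs_run_pipeline(ds, quiet = TRUE)
#' res$physiology
vs_run_pipeline <- function(data, config = vs_config(),
                            registry = vs_registry(), quiet = FALSE) {
  say <- function(stage, msg) {
    if (!quiet) inform(paste0("[", stage, "] ", msg))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("stage `", name, "` failed: ", conditionMessage(e)),
            class = "vs_stage_error", parent = e)
    })
  }
  meta <- tibble::as_tibble(data$meta)
  out <- list()

  # --- equilibration ---------------------------------------------------------
  if (!is.null(data$water)) {
    out$water_enrichment <- stage("equilibration", {
      w <- treatment_water_enrichment(data$water,
                                      window = median(meta$incubation_time))
      say("equilibration", paste0(nrow(w), " treatment x phase enrichment values"))
      w
    })
  }

  sample_water <- function(tracer_id) {
    if (is.null(out$water_enrichment)) {
      abort("no water series provided; soil-water enrichment unavailable.",
            class = "vs_data_error")
    }
    meta |>
      dplyr::inner_join(
        dplyr::filter(out$water_enrichment, .data$tracer == tracer_id),
        by = c("treatment", "phase")) |>
      dplyr::select("sample_id", "soil_water_atpct")
  }

  # --- respiration -----------------------------------------------------------
  if (!is.null(data$headspace)) {
    hs <- tibble::as_tibble(data$headspace)
    hs_lab <- if ("labelling" %in% names(hs)) {
      dplyr::filter(hs, .data$labelling == "labelled")
    } else hs
    out$respiration <- stage("respiration", {
      r <- respiration_rate(hs_lab, meta, config)
      say("respiration", paste0(nrow(r), " samples"))
      r
    })
    if ("labelling" %in% names(hs) && any(hs$labelling == "natural")) {
      out$label_toxicity <- stage("label_toxicity", {
        rn <- respiration_rate(
          dplyr::filter(hs, .data$labelling == "natural"), meta, config)
        paired <- dplyr::inner_join(
          dplyr::select(out$respiration, "sample_id", lab = "respiration"),
          dplyr::select(rn, "sample_id", nat = "respiration"),
          by = "sample_id")
        tt <- paired_t(paired$lab, paired$nat)
        say("label_toxicity",
            sprintf("paired t = %.3f (p = %.4f, n = %d)",
                    tt$statistic, tt$p_value, tt$n))
        tt
      })
    }
  }

  # --- lipid tracer ----------------------------------------------------------
  if (!is.null(data$fame)) {
    out$fame_fluxes <- stage("lipid_flux", {
      fx <- fa_c_produced(data$fame, sample_water("2h"), config)
      say("lipid_flux", paste0(nrow(fx), " marker records (",
                               sum(fx$clamped), " clamped)"))
      fx
    })
    out$lipid_community <- stage("lipid_community", {
      cg <- community_growth(out$fame_fluxes, meta)
      say("lipid_community", paste0(nrow(cg), " sample x fraction rows"))
      cg
    })
    out$group_rates <- stage("group_rates", {
      mass_specific_rates(out$fame_fluxes, meta, registry, quiet = TRUE)
    })
    out$fungi_bacteria <- stage("fungi_bacteria", {
      out$group_rates |>
        dplyr::filter(.data$fraction == "plfa") |>
        dplyr::group_by(.data$sample_id) |>
        dplyr::group_modify(~ tibble::tibble(
          fungi_to_bacteria = fungi_to_bacteria(.x))) |>
        dplyr::ungroup()
    })
    if (any(data$fame$fraction == "nlfa")) {
      out$storage_pct <- stage("storage_pct", {
        nlfa_storage_pct(out$fame_fluxes, registry, quiet = TRUE)
      })
    }
  }

  # --- DNA tracer ------------------------------------------------------------
  if (!is.null(data$dna)) {
    out$dna_growth <- stage("dna_flux", {
      d <- dna_produced(data$dna, sample_water("18o"), config)
      g <- growth_dna(d, meta)
      say("dna_flux", paste0(nrow(g), " DNA samples (",
                             sum(g$clamped), " clamped)"))
      g
    })
  }

  # --- physiology ------------------------------------------------------------
  if (!is.null(out$respiration)) {
    phys <- list()
    if (!is.null(out$lipid_community)) {
      phys$plfa <- physiology_table(out$lipid_community, out$respiration,
                                    meta, tracer = "plfa_2h")
    }
    if (!is.null(out$dna_growth)) {
      phys$dna <- physiology_table(out$dna_growth, out$respiration,
                                   meta, tracer = "dna_18o")
    }
    if (length(phys)) {
      out$physiology <- stage("physiology", {
        p <- dplyr::bind_rows(phys)
        say("physiology", paste0(nrow(p), " sample x tracer rows"))
        p
      })
    }
  }

  # --- treatment summaries ---------------------------------------------------
  if (!is.null(out$physiology)) {
    keyed <- out$physiology |>
      dplyr::left_join(dplyr::select(meta, "sample_id", "treatment", "phase"),
                       by = "sample_id")
    out$contrast_ms_growth <- stage("summaries", {
      keyed |>
        dplyr::group_by(.data$tracer) |>
        dplyr::group_modify(function(d, key) {
          cc <- treatment_contrasts(d, "ms_growth_per_day")
          cc$contrasts
        }) |>
        dplyr::ungroup()
    })
    out$contrast_cue <- stage("summaries", {
      keyed |>
        dplyr::group_by(.data$tracer) |>
        dplyr::group_modify(function(d, key) {
          treatment_contrasts(d, "cue")$contrasts
        }) |>
        dplyr::ungroup()
    })
    out$turnover <- stage("summaries", turnover_table(out$physiology, meta))
  }
  if (!is.null(out$storage_pct)) {
    out$contrast_fungal_storage <- stage("summaries", {
      out$storage_pct |>
        dplyr::filter(.data$group == "fungi") |>
        dplyr::left_join(dplyr::select(meta, "sample_id", "treatment",
                                       "phase"),
                         by = "sample_id") |>
        treatment_contrasts("nlfa_to_plfa_pct") |>
        (\(x) x$contrasts)()
    })
  }
  structure(out, class = "vs_results")
}

#' @export
print.vs_results <- function(x, ...) {
  cat("<vs_results> tables:\n")
  for (nm in names(x)) {
    if (is.data.frame(x[[nm]])) {
      cat(sprintf("  %-24s %d rows\n", nm, nrow(x[[nm]])))
    }
  }
  invisible(x)
}

#' Run the pipeline from a YAML configuration file
#'
#' The configuration names the input CSVs and output directory and may
#' override any [vs_config()] constant:
#' ```yaml
#' inputs:
#'   meta: meta.csv
#'   fame: fame.csv
#'   water: water.csv
#'   dna: dna.csv
#'   headspace: headspace.csv
#' output_dir: results/
#' constants:
#'   a_w: 0.71
#' ```
#'
#' @param config_path Path to the YAML file; relative input paths resolve
#'   against its directory.
#' @param quiet Suppress stage logging.
#' @return The manifest tibble from [write_results()], invisibly the full
#'   result list as attribute `results`.
#' @export
run_pipeline <- function(config_path, quiet = FALSE) {
  cfgy <- yaml::read_yaml(config_path)
  if (is.null(cfgy$inputs) || is.null(cfgy$inputs$meta)) {
    abort("configuration must name at least the metadata table under inputs:.",
          class = "vs_schema_error")
  }
  root <- dirname(normalizePath(config_path))
  resolve <- function(p) if (is.null(p)) NULL else
    if (file.exists(p)) p else file.path(root, p)
  config <- do.call(vs_config, cfgy$constants %||% list())

  data <- list(meta = read_meta_table(resolve(cfgy$inputs$meta)))
  if (!is.null(cfgy$inputs$water)) {
    data$water <- read_water_table(resolve(cfgy$inputs$water))
  }
  if (!is.null(cfgy$inputs$fame)) {
    data$fame <- read_fame_table(resolve(cfgy$inputs$fame), config,
                                 quiet = quiet)
  }
  if (!is.null(cfgy$inputs$dna)) {
    data$dna <- read_dna_table(resolve(cfgy$inputs$dna))
  }
  if (!is.null(cfgy$inputs$headspace)) {
    data$headspace <- read_headspace_table(resolve(cfgy$inputs$headspace))
  }
  results <- vs_run_pipeline(data, config, quiet = quiet)
  out_dir <- resolve(cfgy$output_dir %||% "vaporsip_results")
  manifest <- write_results(results, out_dir)
  attr(manifest, "results") <- results
  manifest
}
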