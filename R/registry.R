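#' Normalize fatty-acid marker names
#'
#' Field spreadsheets write the same marker many ways ("16:1 ω9cis",
#' "16:1w9c", "16:1 W9 CIS"). Normalization strips spaces, maps the omega
#' glyph to "w", collapses "cis"/"trans" suffixes to "c"/"t" and lowercases
#' everything, giving a canonical key for registry lookups.
#'
#' @param marker Character vector of marker names.
#' @return Canonical lowercase marker keys.
#' @export
#' @examples
#' normalize_marker(c("18:1 ω9cis", "10Me16:0", "18:2w6,9"))
normalize_marker <- function(marker) {
  if (any(!nzchar(trimws(marker)) | is.na(marker))) {
    abort("empty marker name.", class = "vs_input_error")
  }
  x <- gsub("\\s+", "", marker)
  x <- gsub("ω", "w", x)
  x <- tolower(x)
  x <- gsub("cis$", "c", x)
  x <- gsub("trans$", "t", x)
  x
}

vs_group_levels <- c("fungi", "amf", "gram_positive", "gram_negative",
                     "actinobacteria", "general")

#' Load a biomarker group registry
#'
#' The registry maps each fatty-acid marker to one microbial group: fungi
#' (18:1w9cis, 18:2w6,9), arbuscular mycorrhizal fungi (16:1w5, kept separate
#' from other fungal markers except for multivariate analyses),
#' actinobacteria (10Me16:0, 10Me17:0, 10Me18:0), other gram-positive
#' bacteria (i15:0, a15:0, i16:0, i17:0, a17:0), gram-negative bacteria
#' (16:1w7, cy17:0, cy19:0), and a general group for markers not assignable
#' to bacteria or fungi (18:1w9trans, 16:0, 17:0, 18:0). Actinobacteria carry
#' `in_gram_positive_sum = TRUE`: gram-positive *sums* are the union of
#' gram_positive and actinobacteria markers.
#'
#' @param path Optional path to a user registry CSV with columns
#'   `marker, group, in_gram_positive_sum, in_multivariate_fungi`; defaults to
#'   the registry shipped with the package.
#' @return Tibble with the registry plus a `marker_norm` key column.
#' @export
vs_registry <- function(path = NULL) {
  path <- path %||% system.file("extdata", "biomarker_groups.csv",
                                package = "vaporsip")
  reg <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("marker", "group", "in_gram_positive_sum", "in_multivariate_fungi")
  miss <- setdiff(req, names(reg))
  if (length(miss)) {
    abort(paste0("registry is missing column(s): ",
                 paste(miss, collapse = ", ")), class = "vs_schema_error")
  }
  bad <- setdiff(unique(reg$group), vs_group_levels)
  if (length(bad)) {
    abort(paste0("unknown group(s) in registry: ", paste(bad, collapse = ", ")),
          class = "vs_schema_error")
  }
  if (any(reg$group == "actinobacteria" & !reg$in_gram_positive_sum)) {
    abort("actinobacteria markers must have in_gram_positive_sum = TRUE.",
          class = "vs_schema_error")
  }
  reg <- dplyr::mutate(reg, marker_norm = normalize_marker(.data$marker))
  if (anyDuplicated(reg$marker_norm)) {
    abort("registry markers are not unique after normalization.",
          class = "vs_schema_error")
  }
  reg
}

#' Assign markers to microbial groups
#'
#' @param marker Character vector of marker names (any common spelling).
#' @param registry Registry tibble from [vs_registry()].
#' @param quiet Suppress the notice for unknown markers.
#' @return Tibble `marker, group, in_gram_positive_sum, in_multivariate_fungi`,
#'   one row per input element, unknown markers assigned to `general`.
#' @export
#' @examples
#' assign_markers(c("18:2ω6,9", "10Me16:0", "16:1ω5"))
assign_markers <- function(marker, registry = vs_registry(), quiet = FALSE) {
  key <- normalize_marker(marker)
  idx <- match(key, registry$marker_norm)
  unknown <- unique(marker[is.na(idx)])
  if (length(unknown) && !quiet) {
    inform(paste0("marker(s) not in registry, assigned to 'general': ",
                  paste(unknown, collapse = ", ")))
  }
  tibble::tibble(
    marker = marker,
    group = ifelse(is.na(idx), "general", registry$group[idx]),
    in_gram_positive_sum = ifelse(is.na(idx), FALSE,
                                  registry$in_gram_positive_sum[idx]),
    in_multivariate_fungi = ifelse(is.na(idx), FALSE,
                                   registry$in_multivariate_fungi[idx])
  )
}

#' Markers belonging to a group
#'
#' Inverse of [assign_markers()]. `gram_positive_sum = TRUE` returns the
#' markers entering gram-positive *sums*, i.e. gram-positive plus
#' actinobacteria markers.
#'
#' @param group One of `r paste(vs_group_levels, collapse = ", ")`.
#' @param registry Registry tibble from [vs_registry()].
#' @param gram_positive_sum Expand `gram_positive` to the summation set.
#' @return Character vector of canonical marker names.
#' @export
group_members <- function(group, registry = vs_registry(),
                          gram_positive_sum = FALSE) {
  group <- match.arg(group, vs_group_levels)
  if (group == "gram_positive" && gram_positive_sum) {
    registry$marker[registry$in_gram_positive_sum]
  } else {
    registry$marker[registry$group == group]
  }
}
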