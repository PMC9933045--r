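study_cols <- c("sample", "metabolite", "fragment", "precursor_index",
                "iso_index", "area")

#' Read a long-format peak-area table
#'
#' Ingests the canonical interchange format: one isotopologue peak per row.
#' Required columns: `sample`, `metabolite`, `iso_index`, `area`; optional:
#' `fragment` and `precursor_index` (both NA for MS1 precursor rows),
#' `group`, `protein_ug`, `control`. Duplicate
#' (sample, metabolite, fragment, precursor_index, iso_index) rows are an
#' error.
#'
#' @param path CSV path.
#' @return A typed study tibble.
#' @export
read_peak_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("Peak table '%s' does not exist.", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("sample", "metabolite", "iso_index", "area")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    abort(sprintf(
      "Peak table '%s' is missing column(s): %s. Expected header: %s.",
      path, paste(missing, collapse = ", "), paste(study_cols, collapse = ", ")))
  }
  if (!"fragment" %in% names(df)) df$fragment <- NA_character_
  if (!"precursor_index" %in% names(df)) df$precursor_index <- NA_integer_
  df <- dplyr::mutate(
    df,
    sample = as.character(.data$sample),
    metabolite = as.character(.data$metabolite),
    fragment = as.character(.data$fragment),
    precursor_index = as.integer(.data$precursor_index),
    iso_index = as.integer(.data$iso_index),
    area = as.numeric(.data$area)
  )
  dup <- duplicated(df[, c("sample", "metabolite", "fragment",
                           "precursor_index", "iso_index")])
  if (any(dup)) {
    first <- df[which(dup)[1], ]
    abort(sprintf(
      "Duplicate peak rows: e.g. sample '%s', metabolite '%s', fragment '%s', iso_index %d.",
      first$sample, first$metabolite,
      ifelse(is.na(first$fragment), "<precursor>", first$fragment),
      first$iso_index))
  }
  df
}

#' Read sample metadata
#'
#' @param path CSV with columns `sample`, `group`, `protein_ug` and optional
#'   `control`.
#' @return A tibble.
#' @export
read_sample_metadata <- function(path) {
  meta <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(c("sample", "group", "protein_ug"), names(meta))
  if (length(missing) > 0L) {
    abort(sprintf("Metadata '%s' is missing column(s): %s.",
                  path, paste(missing, collapse = ", ")))
  }
  if (!"control" %in% names(meta)) meta$control <- FALSE
  meta
}

#' Complete a study table against a metabolite library
#'
#' Fills missing isotopologue indices with zero areas (warning) so every
#' (sample, metabolite) spectrum covers 0..n, and every fragment spectrum
#' 0..n_frag.
#'
#' @param study A study tibble.
#' @param library A `metabolite_library`.
#' @return The completed tibble.
#' @export
complete_study <- function(study, library) {
  meta_cols <- intersect(c("group", "protein_ug", "control"), names(study))
  filled <- study |>
    dplyr::filter(.data$metabolite %in% names(library)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(
      c("sample", meta_cols, "metabolite", "fragment", "precursor_index")))) |>
    dplyr::group_modify(function(rows, key) {
      met <- library[[key$metabolite]]
      n <- if (is.na(key$fragment)) met$n else length(met$fragments[[key$fragment]]$atoms)
      full <- tibble(iso_index = 0:n)
      out <- dplyr::full_join(rows, full, by = "iso_index")
      out$area[is.na(out$area)] <- 0
      dplyr::arrange(out, .data$iso_index)
    }) |>
    dplyr::ungroup()
  n_added <- nrow(filled) - nrow(study[study$metabolite %in% names(library), ])
  if (n_added > 0L) {
    warn(sprintf("Filled %d missing isotopologue row(s) with zero area.", n_added))
  }
  filled
}

#' Write a study table to CSV
#'
#' The write-then-read round trip is lossless for all fields.
#'
#' @param study A study tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_study <- function(study, path) {
  readr::write_csv(study, path, na = "")
  invisible(path)
}

#' Write ground truth to a JSON sidecar
#'
#' @param truth A `ground_truth` (or a list of them).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(path)
}
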