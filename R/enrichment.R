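new_mid <- function(fractions, provenance = c("raw", "corrected")) {
  provenance <- match.arg(provenance)
  if (any(fractions < -1e-12)) abort("MID fractions must be non-negative.")
  fractions <- pmax(fractions, 0)
  s <- sum(fractions)
  if (abs(s - 1) > 1e-9) {
    abort(sprintf("MID fractions must sum to 1 (got %.12g).", s))
  }
  structure(as.numeric(fractions), n = length(fractions) - 1L,
            provenance = provenance, class = "mid")
}

#' @export
print.mid <- function(x, ...) {
  cat(sprintf("<mid> n = %d (%s)\n", attr(x, "n"), attr(x, "provenance")))
  v <- as.numeric(x)
  names(v) <- paste0("M", seq_along(v) - 1L)
  print(round(v, 6))
  invisible(x)
}

#' Normalize isotopologue areas to a mass isotopologue distribution
#'
#' @param areas Non-negative numeric vector of peak areas over mass shifts
#'   `M0..Mn`; at least one entry must be positive.
#' @param provenance `"raw"` (uncorrected areas) or `"corrected"`.
#' @return A `mid` object: fractions summing to 1, with attributes `n` and
#'   `provenance`.
#' @examples
#' normalize_mid(c(1, 1, 2))
#' @export
normalize_mid <- function(areas, provenance = "raw") {
  if (any(!is.finite(areas))) abort("`areas` contains non-finite values.")
  if (any(areas < 0)) abort("`areas` must be non-negative; clamp baselines upstream.")
  if (all(areas == 0)) abort("All areas are zero: empty signal.")
  new_mid(areas / sum(areas), provenance = provenance)
}

#' Mean isotopic enrichment
#'
#' The mean content of tracer atoms that are heavy:
#' `ME = sum_{i=1..n} M_i * i / n`, where `M_i` is the fraction of the
#' isotopologue carrying `i` heavy tracer atoms and `n` the number of tracer
#' atoms in the species. `ME` is 0 for an unlabeled pool and 1 for a fully
#' labeled one.
#'
#' @param mid A `mid` object or a plain fraction vector summing to 1.
#' @return A single number in \[0, 1\].
#' @examples
#' mean_enrichment(c(0.5, 0, 0.5))  # n = 2 -> 0.5
#' @export
mean_enrichment <- function(mid) {
  if (!inherits(mid, "mid")) mid <- new_mid(mid)
  n <- attr(mid, "n")
  if (n == 0L) abort("Mean enrichment is undefined for n = 0.")
  sum(as.numeric(mid) * (0:n)) / n
}

#' Labeled fraction of a pool
#'
#' The fraction of molecules carrying at least one tracer atom: `1 - M0`.
#'
#' @inheritParams mean_enrichment
#' @return A single number in \[0, 1\].
#' @export
labeled_fraction <- function(mid) {
  if (!inherits(mid, "mid")) mid <- new_mid(mid)
  1 - as.numeric(mid)[1]
}

#' Moiety-weighted mean enrichment
#'
#' Combines the enrichments of fragments that tile a molecule (a moiety
#' partition, e.g. glutathione's glutamate moiety F1 and glycine-cysteine
#' moiety F2) into the intact molecule's enrichment:
#' `ME_intact = sum_f ME_f * n_f / sum_f n_f`.
#'
#' @param me Numeric vector of per-moiety mean enrichments.
#' @param atoms Integer vector of per-moiety tracer-atom counts; must sum to
#'   the intact molecule's tracer-atom count.
#' @param n_total Optional intact tracer-atom count to check `atoms` against;
#'   a mismatch means the fragments are not a partition.
#' @return The intact mean enrichment.
#' @examples
#' moiety_weighted_enrichment(c(0.39, 0.04), c(5, 5))  # -> 0.215
#' @export
moiety_weighted_enrichment <- function(me, atoms, n_total = NULL) {
  if (length(me) != length(atoms) || length(me) == 0L) {
    abort("`me` and `atoms` must be non-empty vectors of equal length.")
  }
  if (!is.null(n_total) && sum(atoms) != n_total) {
    abort(paste0(
      "Moiety atom counts do not sum to the intact tracer-atom count; ",
      "the fragments are not a partition. Declare a `partition_group` on ",
      "fragments that tile the molecule."))
  }
  sum(me * atoms) / sum(atoms)
}

#' Floor a fraction to integer percent
#'
#' Report tables print enrichment as integer percent using floor (so 0.215
#' prints as 21). Use `rule = "half_even"` for conventional rounding.
#'
#' @param x Fractions in \[0, 1\].
#' @param rule `"floor"` (default) or `"half_even"`.
#' @return Integer percents.
#' @export
percent_floor <- function(x, rule = c("floor", "half_even")) {
  rule <- match.arg(rule)
  if (rule == "floor") as.integer(floor(100 * x)) else as.integer(round(100 * x))
}

#' Per-spectrum enrichment table for a corrected study
#'
#' Summarises a corrected study table (from [correct_study()]) into one row
#' per (sample, metabolite, source): mean enrichment, labeled fraction, M0
#' and total raw area. For fragments the marginal fragment MID is used —
#' conditional fragment MIDs weighted by the corrected precursor MID (the
#' column sums of the tandem MID).
#'
#' @param corrected Output of [correct_study()].
#' @param library The `metabolite_library` used for correction.
#' @return A tibble with columns `sample` (plus metadata), `metabolite`,
#'   `source` (`"intact"` or the fragment name), `n`, `me`,
#'   `labeled_fraction`, `m0`, `total_area`.
#' @export
enrich_study <- function(corrected, library) {
  meta_cols <- intersect(c("group", "protein_ug", "control"), names(corrected))
  prec <- corrected |>
    dplyr::filter(is.na(.data$fragment), !is.na(.data$fraction)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(
      c("sample", meta_cols, "metabolite")))) |>
    dplyr::summarise(
      source = "intact",
      n = dplyr::n() - 1L,
      me = mean_enrichment(new_mid(.data$fraction[order(.data$iso_index)],
                                   "corrected")),
      labeled_fraction = 1 - .data$fraction[.data$iso_index == 0L],
      m0 = .data$fraction[.data$iso_index == 0L],
      total_area = sum(.data$area),
      .groups = "drop"
    )
  frag_rows <- dplyr::filter(corrected, !is.na(.data$fragment),
                             !is.na(.data$fraction))
  frag <- NULL
  if (nrow(frag_rows) > 0L) {
    prec_mids <- corrected |>
      dplyr::filter(is.na(.data$fragment), !is.na(.data$fraction)) |>
      dplyr::select(dplyr::all_of(c("sample", "metabolite", "iso_index",
                                    "fraction"))) |>
      dplyr::rename(precursor_index = "iso_index",
                    precursor_fraction = "fraction")
    frag <- frag_rows |>
      dplyr::inner_join(prec_mids, by = c("sample", "metabolite",
                                          "precursor_index")) |>
      dplyr::group_by(dplyr::across(dplyr::all_of(
        c("sample", meta_cols, "metabolite", "fragment", "iso_index")))) |>
      # renormalize over the precursor shifts actually measured for this fragment
      dplyr::summarise(
        weighted = sum(.data$fraction * .data$precursor_fraction),
        weight = sum(.data$precursor_fraction) / dplyr::n(),
        area = sum(.data$area),
        .groups = "drop_last"
      ) |>
      dplyr::summarise(
        source = .data$fragment[1],
        n = dplyr::n() - 1L,
        me = mean_enrichment(new_mid(
          {
            v <- .data$weighted[order(.data$iso_index)]
            v / sum(v)
          }, "corrected")),
        labeled_fraction = {
          v <- .data$weighted[order(.data$iso_index)]
          1 - v[1] / sum(v)
        },
        m0 = {
          v <- .data$weighted[order(.data$iso_index)]
          v[1] / sum(v)
        },
        total_area = sum(.data$area),
        .groups = "drop"
      ) |>
      dplyr::select(-dplyr::any_of("fragment"))
  }
  out <- dplyr::bind_rows(prec, frag)
  dplyr::arrange(out, .data$sample, .data$metabolite, .data$source)
}

#' Wide MID table for export
#'
#' One row per (sample, metabolite, source) with `M0..Mn` fraction columns,
#' mean enrichment and labeled fraction; the CSV-friendly companion of
#' [enrich_study()].
#'
#' @inheritParams enrich_study
#' @return A tibble with `M0..Mmax` columns (NA beyond a species' own n).
#' @export
mid_table <- function(corrected, library) {
  meta_cols <- intersect(c("group", "protein_ug", "control"), names(corrected))
  corrected |>
    dplyr::filter(!is.na(.data$fraction)) |>
    dplyr::mutate(source = dplyr::coalesce(.data$fragment, "intact")) |>
    dplyr::filter(is.na(.data$fragment)) |>
    dplyr::select(dplyr::all_of(c("sample", meta_cols, "metabolite", "source",
                                  "iso_index", "fraction"))) |>
    tidyr::pivot_wider(names_from = "iso_index", values_from = "fraction",
                       names_prefix = "M") |>
    dplyr::left_join(
      enrich_study(corrected, library) |>
        dplyr::select(dplyr::all_of(c("sample", "metabolite", "source", "me",
                                      "labeled_fraction"))),
      by = c("sample", "metabolite", "source")
    )
}
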