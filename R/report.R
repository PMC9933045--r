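#' Normalize peak areas by sample protein content
#'
#' Divides each area by the sample's protein content (µg), putting samples of
#' different cell mass on a common scale. Samples with missing or
#' non-positive protein values are excluded with a warning.
#'
#' @param df A tibble with columns `area` and `protein_ug`.
#' @return The tibble with a `norm_area` column (area per µg protein),
#'   excluded samples dropped.
#' @export
normalize_by_protein <- function(df) {
  bad <- is.na(df$protein_ug) | df$protein_ug <= 0
  if (any(bad)) {
    warn(sprintf("Excluding %d sample row(s) with missing or non-positive protein content.",
                 sum(bad)))
    df <- df[!bad, , drop = FALSE]
  }
  dplyr::mutate(df, norm_area = .data$area / .data$protein_ug)
}

#' Split a pool into unlabeled and labeled channels
#'
#' Partitions a metabolite's total area into the unlabeled channel (the
#' corrected M0 fraction of the pool) and the labeled channel (everything
#' carrying at least one tracer atom): `unlabeled = M0 * area`,
#' `labeled = (1 - M0) * area`. The two channels conserve the total exactly.
#'
#' @param mid A `mid` (corrected) or its M0 fraction as a single number.
#' @param area Total (typically protein-normalized) peak area of the pool.
#' @return Named numeric: `unlabeled`, `labeled`.
#' @export
channel_pools <- function(mid, area) {
  m0 <- if (inherits(mid, "mid") || length(mid) > 1L) as.numeric(mid)[1] else mid
  c(unlabeled = m0 * area, labeled = (1 - m0) * area)
}

#' Per-sample channel pool table
#'
#' @param enriched Output of [enrich_study()] (intact rows are used).
#' @param normalize Divide by protein content first (default TRUE).
#' @return Tibble: sample, metadata, metabolite, `unlabeled_pool`,
#'   `labeled_pool`, `total`.
#' @export
pool_table <- function(enriched, normalize = TRUE) {
  df <- dplyr::filter(enriched, .data$source == "intact")
  if (normalize) {
    df <- df |>
      dplyr::rename(area = "total_area") |>
      normalize_by_protein() |>
      dplyr::rename(total_area = "area")
    df$total <- df$norm_area
  } else {
    df$total <- df$total_area
  }
  df |>
    dplyr::mutate(unlabeled_pool = .data$m0 * .data$total,
                  labeled_pool = (1 - .data$m0) * .data$total) |>
    dplyr::select(-dplyr::any_of(c("norm_area", "source", "n", "me",
                                   "labeled_fraction")))
}

#' GSH/GSSG peak-area ratio per channel
#'
#' The ratio of the reduced to the oxidized glutathione pool in the same
#' labeling channel (12C-GSH / 12C-GSSG and 13C-GSH / 13C-GSSG). A low ratio
#' indexes oxidative stress. Zero denominators yield `NA`, never infinity.
#'
#' @param pools Output of [pool_table()] containing both metabolites.
#' @param gsh,gssg Metabolite names of the reduced and oxidized species.
#' @return Tibble: sample, metadata, `channel` (`"unlabeled"`/`"labeled"`),
#'   `ratio`.
#' @export
gsh_gssg_ratio <- function(pools, gsh = "glutathione", gssg = "gssg") {
  meta_cols <- intersect(c("group", "control"), names(pools))
  wide <- pools |>
    dplyr::filter(.data$metabolite %in% c(gsh, gssg)) |>
    dplyr::select(dplyr::all_of(c("sample", meta_cols, "metabolite",
                                  "unlabeled_pool", "labeled_pool"))) |>
    tidyr::pivot_longer(dplyr::all_of(c("unlabeled_pool", "labeled_pool")),
                        names_to = "channel", values_to = "pool") |>
    dplyr::mutate(channel = sub("_pool$", "", .data$channel)) |>
    tidyr::pivot_wider(names_from = "metabolite", values_from = "pool")
  if (!all(c(gsh, gssg) %in% names(wide))) {
    abort(sprintf("Both '%s' and '%s' must be present to form a ratio.", gsh, gssg))
  }
  wide |>
    dplyr::mutate(ratio = dplyr::if_else(.data[[gssg]] > 0,
                                         .data[[gsh]] / .data[[gssg]],
                                         NA_real_)) |>
    dplyr::select(-dplyr::all_of(c(gsh, gssg)))
}

#' Labeled fraction of the combined GSH + GSSG pool
#'
#' Pools reduced and oxidized glutathione by corrected-area weighting:
#' `labeled = sum((1 - M0_m) * area_m) / sum(area_m)` over the two
#' metabolites. If one metabolite is missing the fraction is computed on the
#' present one with a warning.
#'
#' @inheritParams gsh_gssg_ratio
#' @return Tibble: sample, metadata, `unlabeled_fraction`,
#'   `labeled_fraction`.
#' @export
combined_labeled_fraction <- function(pools, gsh = "glutathione",
                                      gssg = "gssg") {
  meta_cols <- intersect(c("group", "control"), names(pools))
  df <- dplyr::filter(pools, .data$metabolite %in% c(gsh, gssg))
  present <- unique(df$metabolite)
  if (length(present) < 2L) {
    warn(sprintf("Only '%s' present; combined fraction computed on it alone.",
                 paste(present, collapse = ", ")))
  }
  df |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("sample", meta_cols)))) |>
    dplyr::summarise(
      labeled_fraction = sum(.data$labeled_pool) / sum(.data$total),
      unlabeled_fraction = sum(.data$unlabeled_pool) / sum(.data$total),
      .groups = "drop"
    )
}

#' Two-group comparison (Welch's t-test)
#'
#' Two-sided Welch's t-test (unequal variances) between two groups of
#' values, flagged at `alpha`. With fewer than two values in either group
#' the test is skipped and the flag is `NA`.
#'
#' @param values_a,values_b Numeric vectors of per-sample values.
#' @param alpha Significance level (default 0.05).
#' @return One-row tibble: `mean_a`, `mean_b`, `sd_a`, `sd_b`, `statistic`,
#'   `p_value`, `significant`.
#' @examples
#' compare_groups(c(10, 11, 9, 10, 12), c(6, 7, 5, 6, 8))
#' @export
compare_groups <- function(values_a, values_b, alpha = 0.05) {
  values_a <- values_a[is.finite(values_a)]
  values_b <- values_b[is.finite(values_b)]
  base <- tibble(
    n_a = length(values_a), n_b = length(values_b),
    mean_a = mean(values_a), mean_b = mean(values_b),
    sd_a = stats::sd(values_a), sd_b = stats::sd(values_b)
  )
  if (length(values_a) < 2L || length(values_b) < 2L) {
    return(dplyr::mutate(base, statistic = NA_real_, p_value = NA_real_,
                         significant = NA))
  }
  if (stats::sd(values_a) == 0 && stats::sd(values_b) == 0) {
    # degenerate: Welch undefined; identical constants are not different
    p <- if (isTRUE(all.equal(mean(values_a), mean(values_b)))) 1 else 0
    return(dplyr::mutate(base, statistic = NA_real_, p_value = p,
                         significant = p < alpha))
  }
  tt <- stats::t.test(values_a, values_b, var.equal = FALSE)
  dplyr::mutate(base, statistic = unname(tt$statistic),
                p_value = tt$p.value, significant = tt$p.value < alpha)
}

#' Groupwise comparisons across a study table
#'
#' Runs [compare_groups()] for every stratum of a long table (e.g. per
#' metabolite, per channel), comparing the two levels of `group`.
#'
#' @param df A tibble with a `group` column (exactly two non-control levels)
#'   and the value column.
#' @param value Name of the value column (string).
#' @param by Character vector of stratifying columns.
#' @param alpha Significance level.
#' @param adjust Multiple-testing adjustment passed to [stats::p.adjust()]
#'   (`"none"` by default, mirroring per-panel significance flags; use
#'   `"BH"` for Benjamini-Hochberg).
#' @return Tibble with one row per stratum plus the [compare_groups()]
#'   columns and `p_adjusted`.
#' @export
group_comparisons <- function(df, value, by, alpha = 0.05, adjust = "none") {
  if ("control" %in% names(df)) df <- dplyr::filter(df, !.data$control)
  levels <- unique(df$group)
  if (length(levels) != 2L) {
    abort(sprintf("`group` must have exactly 2 levels, found %d.", length(levels)))
  }
  run_test <- function(rows, ...) {
    compare_groups(rows[[value]][rows$group == levels[1]],
                   rows[[value]][rows$group == levels[2]],
                   alpha = alpha)
  }
  out <- if (length(by) == 0L) {
    run_test(df)
  } else {
    df |>
      dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
      dplyr::group_modify(run_test) |>
      dplyr::ungroup()
  }
  out$p_adjusted <- stats::p.adjust(out$p_value, method = adjust)
  if (adjust != "none") out$significant <- out$p_adjusted < alpha
  out
}

#' Pathway enrichment summary
#'
#' Mean +/- SD of mean isotopic enrichment per metabolite, source and group
#' — the machine-readable analogue of an atom-flow pathway map annotated
#' with enrichments. Metabolites whose mean enrichment is indistinguishable
#' from zero are flagged `no_incorporation` (e.g. cysteine under both
#' tracers, glycine under 15N), marking pools supplied independently of the
#' tracer.
#'
#' @param enriched Output of [enrich_study()].
#' @param threshold Mean enrichment below which a pool is flagged as showing
#'   no tracer incorporation.
#' @return Tibble: `group`, `metabolite`, `source`, `n_samples`, `me_mean`,
#'   `me_sd`, `me_pct` (integer percent, floor rule), `no_incorporation`.
#' @export
enrichment_summary <- function(enriched, threshold = 0.005) {
  df <- enriched
  if ("control" %in% names(df)) df <- dplyr::filter(df, !.data$control)
  df |>
    dplyr::group_by(dplyr::across(dplyr::any_of(c("group", "metabolite",
                                                  "source")))) |>
    dplyr::summarise(
      n_samples = dplyr::n(),
      me_mean = mean(.data$me),
      me_sd = stats::sd(.data$me),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      me_pct = percent_floor(.data$me_mean),
      no_incorporation = .data$me_mean < threshold
    )
}
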