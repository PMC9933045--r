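#' Plot mass isotopologue distributions
#'
#' Bar chart of corrected isotopologue fractions per metabolite, averaged
#' over samples within group.
#'
#' @param corrected Output of [correct_study()].
#' @param metabolites Optional subset of metabolites to show.
#' @return A ggplot object.
#' @export
plot_mid <- function(corrected, metabolites = NULL) {
  df <- dplyr::filter(corrected, is.na(.data$fragment), !is.na(.data$fraction))
  if ("control" %in% names(df)) df <- dplyr::filter(df, !.data$control)
  if (!is.null(metabolites)) {
    df <- dplyr::filter(df, .data$metabolite %in% metabolites)
  }
  grp <- if ("group" %in% names(df)) "group" else NULL
  df <- df |>
    dplyr::group_by(dplyr::across(dplyr::all_of(
      c(grp, "metabolite", "iso_index")))) |>
    dplyr::summarise(fraction = mean(.data$fraction), .groups = "drop")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$iso_index,
                                        y = .data$fraction)) +
    ggplot2::geom_col(ggplot2::aes(fill = if (is.null(grp)) NULL else .data$group),
                      position = "dodge") +
    ggplot2::facet_wrap(~metabolite, scales = "free_x") +
    ggplot2::labs(x = "mass shift (M+i)", y = "isotopologue fraction",
                  fill = NULL) +
    ggplot2::theme_minimal()
  p
}

#' Plot a pathway enrichment summary
#'
#' Mean enrichment per metabolite and group with SD error bars.
#'
#' @param summary Output of [enrichment_summary()].
#' @param source Which source rows to show (default `"intact"`).
#' @return A ggplot object.
#' @export
plot_enrichment <- function(summary, source = "intact") {
  df <- dplyr::filter(summary, .data$source == !!source)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metabolite, y = .data$me_mean,
                                   fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$me_mean - .data$me_sd,
                   ymax = .data$me_mean + .data$me_sd),
      position = ggplot2::position_dodge(width = 0.9), width = 0.3) +
    ggplot2::labs(x = NULL, y = "mean isotopic enrichment", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @describeIn resolve_isotopomer_fractions Bar chart of resolved weights.
#' @param object An `isotopomer_fit`.
#' @param ... Unused.
#' @method autoplot isotopomer_fit
#' @export
autoplot.isotopomer_fit <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$isotopomer, y = .data$weight)) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = NULL, y = "isotopomer weight",
      subtitle = if (object$identifiable) NULL else "not identifiable") +
    ggplot2::theme_minimal()
}

#' @describeIn assemble_tandem_mid Heatmap of the joint precursor x fragment
#'   distribution.
#' @param object A `tandem_mid`.
#' @param ... Unused.
#' @method autoplot tandem_mid
#' @export
autoplot.tandem_mid <- function(object, ...) {
  m <- unclass(object)
  df <- tibble(
    precursor = rep(seq_len(nrow(m)) - 1L, times = ncol(m)),
    fragment = rep(seq_len(ncol(m)) - 1L, each = nrow(m)),
    fraction = as.vector(m)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fragment, y = .data$precursor,
                                   fill = .data$fraction)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = sprintf("fragment shift (%s)", attr(object, "fragment")),
                  y = "precursor shift", fill = "fraction") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
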