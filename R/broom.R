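#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an isotopomer fit
#'
#' One row per candidate isotopomer with its resolved weight.
#'
#' @param x An `isotopomer_fit` from [resolve_isotopomer_fractions()].
#' @param ... Unused.
#' @return Tibble: `isotopomer`, `atoms`, `weight`, `shift`.
#' @method tidy isotopomer_fit
#' @export
tidy.isotopomer_fit <- function(x, ...) {
  tibble(
    isotopomer = names(x$weights),
    atoms = vapply(x$candidates, paste, character(1), collapse = "+"),
    weight = unname(x$weights),
    shift = x$shift
  )
}

#' Glance at an isotopomer fit
#'
#' @param x An `isotopomer_fit`.
#' @param ... Unused.
#' @return One-row tibble: `shift`, `n_candidates`, `residual`, `rank`,
#'   `identifiable`.
#' @method glance isotopomer_fit
#' @export
glance.isotopomer_fit <- function(x, ...) {
  tibble(
    shift = x$shift,
    n_candidates = length(x$weights),
    residual = x$residual,
    rank = x$rank,
    identifiable = x$identifiable
  )
}

#' Tidy a correction matrix
#'
#' Long-format entries of the forward convolution matrix.
#'
#' @param x A `correction_matrix`.
#' @param ... Unused.
#' @return Tibble: `observed_shift`, `true_shift`, `probability`.
#' @method tidy correction_matrix
#' @export
tidy.correction_matrix <- function(x, ...) {
  m <- as.matrix(x)
  tibble(
    observed_shift = rep(0:x$n, times = x$n + 1L),
    true_shift = rep(0:x$n, each = x$n + 1L),
    probability = as.vector(m)
  ) |>
    dplyr::filter(.data$probability > 0)
}

#' Glance at a correction matrix
#'
#' @param x A `correction_matrix`.
#' @param ... Unused.
#' @return One-row tibble: `n`, `mode`, `kind`, `element`, `condition`
#'   (kappa, a conditioning diagnostic for the inversion).
#' @method glance correction_matrix
#' @export
glance.correction_matrix <- function(x, ...) {
  tibble(
    n = x$n, mode = x$mode, kind = x$kind, element = x$tracer$element,
    condition = kappa(as.matrix(x), exact = TRUE)
  )
}

#' Tidy a ground truth
#'
#' @param x A `ground_truth` from [generate_ground_truth()].
#' @param ... Unused.
#' @return Tibble: `metabolite`, `isotopomer` (atom key), `fraction`.
#' @method tidy ground_truth
#' @export
tidy.ground_truth <- function(x, ...) {
  purrr::imap_dfr(x, function(tr, nm) {
    if (is.null(tr$isotopomers)) {
      return(tibble(metabolite = nm, isotopomer = NA_character_,
                    fraction = NA_real_))
    }
    tibble(metabolite = nm, isotopomer = names(tr$isotopomers),
           fraction = unname(tr$isotopomers))
  })
}

#' Glance at a ground truth
#'
#' @param x A `ground_truth`.
#' @param ... Unused.
#' @return Tibble: `metabolite`, `n`, `me` (true mean enrichment).
#' @method glance ground_truth
#' @export
glance.ground_truth <- function(x, ...) {
  purrr::imap_dfr(x, function(tr, nm) {
    tibble(metabolite = nm, n = length(tr$mid) - 1L, me = tr$me)
  })
}
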