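#' Correction matrices for isotopologue measurements
#'
#' An observed mass isotopologue distribution is the true tracer-labeling
#' distribution convolved with (i) natural heavy-isotope abundance at
#' unlabeled positions and (ii) incomplete isotopic purity of the tracer
#' substrate. Both effects are linear: `m = F x` with `F` column-stochastic.
#' These builders construct `F`; [correct_mid()] inverts it.
#'
#' In `high_resolution_tracer_only` mode (the default, appropriate when the
#' mass analyzer resolves tracer-element isotopologues from other-element
#' isotope peaks) only the tracer element contributes:
#' `F[i,j] = C(n-j, i-j) a^(i-j) (1-a)^(n-i)` for `i >= j`, where `a` is the
#' natural heavy-isotope abundance and `n-j` the unlabeled positions.
#' In `low_resolution_full_formula` mode the isotope patterns of all
#' non-tracer elements of the supplied formula are additionally convolved
#' over nominal mass shifts; mass shifted beyond `n` falls outside the
#' measured window and columns are renormalized.
#'
#' @param n Number of tracer atoms (>= 1).
#' @param tracer A [tracer_spec()].
#' @param mode `"high_resolution_tracer_only"` or
#'   `"low_resolution_full_formula"`.
#' @param formula Elemental formula of the measured species; required in
#'   low-resolution mode.
#' @return A `correction_matrix` object.
#' @examples
#' natural_abundance_matrix(5, tracer_spec("C"))
#' @name correction-matrices
NULL

.correction_modes <- c("high_resolution_tracer_only", "low_resolution_full_formula")

new_correction_matrix <- function(F, mode, tracer, n, kind) {
  stopifnot(nrow(F) == n + 1, ncol(F) == n + 1)
  dimnames(F) <- list(paste0("M", 0:n), paste0("M", 0:n))
  structure(list(matrix = F, mode = mode, tracer = tracer, n = n, kind = kind),
            class = "correction_matrix")
}

#' @export
as.matrix.correction_matrix <- function(x, ...) x$matrix

#' @export
print.correction_matrix <- function(x, ...) {
  cat(sprintf("<correction_matrix> %s, n = %d, mode = %s (%s tracer)\n",
              x$kind, x$n, x$mode, x$tracer$element))
  print(round(x$matrix, 6))
  invisible(x)
}

#' @rdname correction-matrices
#' @export
natural_abundance_matrix <- function(n, tracer,
                                     mode = .correction_modes,
                                     formula = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(n) || n < 1) abort("`n` must be >= 1 (no tracer atoms, nothing to correct).")
  n <- as.integer(n)
  a <- tracer$natural_abundance
  F <- matrix(0, n + 1, n + 1)
  for (j in 0:n) {
    # i - j extra heavy atoms among the n - j unlabeled tracer positions
    F[(j:n) + 1, j + 1] <- stats::dbinom(0:(n - j), n - j, a)
  }
  if (mode == "low_resolution_full_formula") {
    if (is.null(formula)) {
      abort("Low-resolution mode needs the species' elemental `formula`.")
    }
    if (is.character(formula)) formula <- parse_formula(formula)
    env_pattern <- non_tracer_pattern(formula, tracer$element)
    F <- apply(F, 2, function(col) {
      full <- conv_vec(col, env_pattern)
      out <- full[seq_len(n + 1)]
      out / sum(out)  # mass beyond M+n is outside the measured window
    })
  }
  new_correction_matrix(F, mode, tracer, n, "natural_abundance")
}

# Nominal-mass-shift distribution contributed by all non-tracer atoms.
non_tracer_pattern <- function(formula, tracer_element) {
  pattern <- 1
  for (el in names(formula)) {
    count <- if (el == tracer_element) 0L else as.integer(formula[[el]])
    if (count == 0L) next
    single <- .isotope_patterns[[el]]
    for (k in seq_len(count)) pattern <- conv_vec(pattern, single)
  }
  pattern
}

conv_vec <- function(x, y) {
  out <- numeric(length(x) + length(y) - 1L)
  for (i in seq_along(x)) {
    out[i:(i + length(y) - 1L)] <- out[i:(i + length(y) - 1L)] + x[i] * y
  }
  out
}

#' @rdname correction-matrices
#' @export
purity_matrix <- function(n, tracer) {
  if (!is.numeric(n) || n < 1) abort("`n` must be >= 1.")
  n <- as.integer(n)
  p <- tracer$purity
  if (p <= 0) abort("Tracer purity 0 gives a degenerate (all-unlabeled) matrix.")
  F <- matrix(0, n + 1, n + 1)
  for (j in 0:n) {
    # each of j nominally labeled atoms is actually heavy with probability p
    F[(0:j) + 1, j + 1] <- stats::dbinom(0:j, j, p)
  }
  new_correction_matrix(F, "high_resolution_tracer_only", tracer, n, "purity")
}

#' Combined forward correction matrix
#'
#' `F_total = F_nat %*% F_purity`: tracer impurity acts on the nominal
#' labeling first, natural abundance then decorates the remaining light
#' positions. The composition order is fixed; the two matrices only commute
#' for `n = 1`.
#'
#' @inheritParams correction-matrices
#' @return A `correction_matrix` of kind `"combined"`.
#' @export
correction_matrix <- function(n, tracer, mode = .correction_modes,
                              formula = NULL) {
  mode <- match.arg(mode)
  Fn <- natural_abundance_matrix(n, tracer, mode, formula)
  Fp <- purity_matrix(n, tracer)
  new_correction_matrix(Fn$matrix %*% Fp$matrix, mode, tracer, as.integer(n),
                        "combined")
}

#' Correct a measured isotopologue vector
#'
#' Recovers the true tracer-labeling distribution from measured isotopologue
#' peak areas by non-negative least squares: solves
#' `min || F x - m ||^2` subject to `x >= 0`, then renormalizes `x` to sum 1.
#' Plain matrix inversion is never used — under noise it yields negative
#' fractions. Negative measured areas (baseline-subtraction artifacts) are
#' clamped to zero with a warning.
#'
#' @param measured Numeric vector of length `n + 1` of peak areas (or
#'   fractions) over mass shifts `M0..Mn`.
#' @param cmat A `correction_matrix` (typically from [correction_matrix()]).
#' @param residual_threshold Relative residual above which the result is
#'   flagged (not an error): `||F x - m|| / ||m||`.
#' @return A `mid` object (see [normalize_mid()]) with provenance
#'   `"corrected"` and attributes `residual` (relative) and `flagged`.
#' @examples
#' tr <- tracer_spec("C", purity = 0.99)
#' F <- correction_matrix(5, tr)
#' truth <- c(0.2, 0, 0.5, 0, 0, 0.3)
#' observed <- as.numeric(as.matrix(F) %*% truth)
#' correct_mid(observed, F)
#' @export
correct_mid <- function(measured, cmat, residual_threshold = 0.05) {
  F <- as.matrix(cmat)
  if (length(measured) != nrow(F)) {
    abort(sprintf("`measured` has length %d but the matrix expects %d (n = %d).",
                  length(measured), nrow(F), nrow(F) - 1L))
  }
  if (any(!is.finite(measured))) abort("`measured` contains non-finite values.")
  if (any(measured < 0)) {
    warn(sprintf("Clamping %d negative measured area(s) to zero.",
                 sum(measured < 0)))
    measured[measured < 0] <- 0
  }
  if (all(measured == 0)) abort("All measured areas are zero: empty signal.")
  scale <- sum(measured)
  m <- measured / scale
  fit <- pracma::lsqnonneg(F, m)
  x <- fit$x
  if (sum(x) <= 0) abort("Correction produced an all-zero solution.")
  residual <- sqrt(sum((F %*% x - m)^2)) / sqrt(sum(m^2))
  x <- x / sum(x)
  out <- new_mid(x, provenance = "corrected")
  attr(out, "residual") <- residual
  attr(out, "flagged") <- residual > residual_threshold
  if (attr(out, "flagged")) {
    warn(sprintf("Correction residual %.3g exceeds threshold %.3g; result flagged.",
                 residual, residual_threshold))
  }
  out
}

#' Export a correction matrix to CSV for inspection
#'
#' @param cmat A `correction_matrix`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_correction_matrix <- function(cmat, path) {
  df <- as_tibble(as.matrix(cmat), rownames = "observed_shift")
  readr::write_csv(df, path)
  invisible(path)
}

#' Correct a study table
#'
#' Applies [correct_mid()] to every spectrum in a long-format study table:
#' each (sample, metabolite) precursor MID and each (sample, metabolite,
#' fragment, precursor shift) conditional fragment MID. Precursors are
#' corrected with a matrix of size the metabolite's tracer-atom count;
#' fragment spectra with a matrix of the fragment's retained-atom count,
#' independently of the precursor selection (the conditioning on precursor
#' shift is retained, the correction itself is per-fragment).
#'
#' @param study A study tibble with columns `sample`, `metabolite`,
#'   `fragment` (NA for precursor rows), `precursor_index` (NA for precursor
#'   rows), `iso_index`, `area` (plus any metadata columns, carried through).
#' @param library A `metabolite_library`.
#' @param tracer A [tracer_spec()].
#' @param mode Correction mode, see [correction-matrices].
#' @param residual_threshold Passed to [correct_mid()].
#' @return A tibble like `study` with columns `fraction` (corrected
#'   isotopologue fraction), `residual` and `flagged` added. Metabolites not
#'   present in `library` are dropped with a warning.
#' @export
correct_study <- function(study, library, tracer,
                          mode = .correction_modes,
                          residual_threshold = 0.05) {
  mode <- match.arg(mode)
  unknown <- setdiff(unique(study$metabolite), names(library))
  if (length(unknown) > 0L) {
    warn(sprintf("Dropping undeclared metabolite(s): %s.",
                 paste(unknown, collapse = ", ")))
    study <- dplyr::filter(study, .data$metabolite %in% names(library))
  }
  # cache matrices per (metabolite, fragment)
  cache <- new.env(parent = emptyenv())
  get_matrix <- function(met_name, frag_name) {
    key <- paste(met_name, frag_name %||% ".precursor", sep = "\r")
    if (!is.null(cache[[key]])) return(cache[[key]])
    met <- library[[met_name]]
    if (is.null(frag_name) || is.na(frag_name)) {
      cm <- correction_matrix(met$n, tracer, mode, met$formula)
    } else {
      frag <- met$fragments[[frag_name]]
      if (is.null(frag)) {
        abort(sprintf("Fragment '%s' is not declared for metabolite '%s'.",
                      frag_name, met_name))
      }
      cm <- correction_matrix(length(frag$atoms), tracer, mode, frag$formula)
    }
    cache[[key]] <- cm
    cm
  }
  study |>
    dplyr::group_by(dplyr::across(dplyr::any_of(
      c("sample", "group", "protein_ug", "control", "metabolite",
        "fragment", "precursor_index")))) |>
    dplyr::group_modify(function(rows, key) {
      cm <- get_matrix(key$metabolite, key$fragment)
      rows <- dplyr::arrange(rows, .data$iso_index)
      areas <- numeric(cm$n + 1)
      areas[rows$iso_index + 1L] <- rows$area
      if (all(areas == 0)) {
        return(dplyr::mutate(rows, fraction = NA_real_,
                             residual = NA_real_, flagged = NA))
      }
      mid <- correct_mid(areas, cm, residual_threshold)
      tibble(
        iso_index = 0:cm$n,
        area = areas,
        fraction = as.numeric(mid),
        residual = attr(mid, "residual"),
        flagged = attr(mid, "flagged")
      )
    }) |>
    dplyr::ungroup()
}
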