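#' Predicted fragment mass shift of a positional isotopomer
#'
#' A fragment retains the subset of labeled atoms that fall inside its atom
#' map: the predicted fragment shift of isotopomer `s` is `|s intersect
#' atom_subset|`. This is the link that lets MS2 fragments distinguish
#' isotopomers with equal precursor mass — e.g. 1,2-13C2-glutamate puts one
#' heavy atom into Frag_1 (c2-c5) while 3,4-13C2-glutamate puts two.
#'
#' @param isotopomer Character vector of labeled atom positions.
#' @param frag A [fragment_def()].
#' @return Integer shift count.
#' @examples
#' lib <- gsh_pathway_library("C")
#' predict_fragment_shift(c("c1", "c2"), lib$glutamate$fragments$Frag_1)  # 1
#' @export
predict_fragment_shift <- function(isotopomer, frag) {
  length(intersect(isotopomer, frag$atoms))
}

#' Enumerate candidate positional isotopomers for a precursor shift
#'
#' Returns the declared candidates for mass shift `j` if the metabolite
#' configures any (the biochemically informed route), otherwise all
#' `choose(n, j)` position subsets in lexicographic order (a fallback that is
#' almost always rank-deficient for the declared fragments and will be
#' flagged unidentifiable by the solver).
#'
#' @param met A [metabolite_def()].
#' @param j Precursor mass shift, `0 <= j <= n`.
#' @param candidates Optional explicit list of atom-label vectors overriding
#'   the metabolite's declaration.
#' @return List of character vectors (class `isotopomer_set`).
#' @export
enumerate_isotopomers <- function(met, j, candidates = NULL) {
  if (j < 0 || j > met$n) {
    abort(sprintf("Precursor shift %d outside 0..%d for '%s'.", j, met$n, met$name))
  }
  declared <- candidates %||% met$isotopomers[[as.character(j)]]
  if (!is.null(declared)) {
    for (s in declared) {
      if (length(s) != j) {
        abort(sprintf(
          "Declared isotopomer {%s} of '%s' has %d labeled atoms but explains shift %d.",
          paste(s, collapse = ","), met$name, length(s), j))
      }
      bad <- setdiff(s, met$atoms)
      if (length(bad) > 0L) {
        abort(sprintf("Isotopomer of '%s' references unknown atom(s): %s.",
                      met$name, paste(bad, collapse = ", ")))
      }
    }
    out <- declared
  } else if (j == 0L) {
    out <- list(character(0))
  } else {
    out <- utils::combn(met$atoms, j, simplify = FALSE)
  }
  structure(out, class = "isotopomer_set", metabolite = met$name, shift = j)
}

#' Human-readable isotopomer label
#'
#' `c("c1","c2")` with a carbon tracer becomes `"1,2-13C2"`; the empty set is
#' `"M+0"`.
#'
#' @param atoms Character vector of labeled atom positions.
#' @param element Tracer element symbol.
#' @return A string.
#' @export
isotopomer_label <- function(atoms, element = "C") {
  if (length(atoms) == 0L) return("M+0")
  pos <- sort(as.integer(sub("^[a-z]+", "", atoms)))
  iso <- if (element == "C") "13C" else "15N"
  sprintf("%s-%s%d", paste(pos, collapse = ","), iso, length(atoms))
}

#' Assemble a tandem MID
#'
#' The tandem MID is the joint distribution `T[j, k]` of precursor mass
#' shift `j` and fragment mass shift `k`: `T[j, k] = precursor_mid[j] *
#' conditional[[j]][k]`. Rows for precursor shifts without a measured
#' fragment spectrum are zero-filled and recorded in the `missing_rows`
#' attribute.
#'
#' @param precursor_mid A `mid` (corrected precursor MID, length `n + 1`).
#' @param conditional Named list keyed by precursor shift `j` (as character);
#'   each element the corrected conditional fragment MID (length
#'   `n_frag + 1`).
#' @param frag The [fragment_def()] the conditionals belong to.
#' @return A `tandem_mid`: matrix of dimension `(n+1) x (n_frag+1)` with
#'   attributes `fragment` and `missing_rows`.
#' @export
assemble_tandem_mid <- function(precursor_mid, conditional, frag) {
  if (!inherits(precursor_mid, "mid")) precursor_mid <- new_mid(precursor_mid)
  n <- attr(precursor_mid, "n")
  nf <- length(frag$atoms)
  keys <- as.integer(names(conditional))
  if (any(is.na(keys)) || any(keys < 0 | keys > n)) {
    abort("`conditional` keys must be precursor shifts in 0..n.")
  }
  T <- matrix(0, n + 1L, nf + 1L,
              dimnames = list(paste0("M", 0:n), paste0("m", 0:nf)))
  for (i in seq_along(conditional)) {
    cond <- as.numeric(conditional[[i]])
    if (length(cond) != nf + 1L) {
      abort(sprintf(
        "Conditional MID at precursor shift %d has length %d; fragment '%s' needs %d.",
        keys[i], length(cond), frag$name, nf + 1L))
    }
    T[keys[i] + 1L, ] <- as.numeric(precursor_mid)[keys[i] + 1L] * cond
  }
  missing_rows <- setdiff(which(as.numeric(precursor_mid) > 1e-12) - 1L, keys)
  structure(T, class = "tandem_mid", fragment = frag$name,
            missing_rows = missing_rows)
}

#' @export
print.tandem_mid <- function(x, ...) {
  cat(sprintf("<tandem_mid> fragment %s\n", attr(x, "fragment")))
  print(round(unclass(x), 6))
  miss <- attr(x, "missing_rows")
  if (length(miss)) {
    cat("Zero-filled precursor shifts (no fragment spectrum): ",
        paste(miss, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Resolve positional isotopomer fractions at a precursor shift
#'
#' Given the corrected conditional fragment MIDs observed at precursor shift
#' `j` for one or more fragments, and a set of candidate isotopomers, solves
#' for the isotopomer weights by constrained linear least squares. The design
#' matrix has one row per (fragment, fragment shift) and one column per
#' candidate: `A[(f,k), s] = 1` if [predict_fragment_shift()] of `s` through
#' `f` equals `k`. The solve is `min ||A w - b||^2` subject to `w >= 0`,
#' `sum(w) = 1`, with `b` the stacked observed conditionals. All fragments
#' are solved jointly in one stacked system: a fragment that merely forbids a
#' shift (an impossible peak) still adds information.
#'
#' Identifiability is `rank([A; 1']) >= #candidates`; rank deficiency never
#' raises — the returned weights are one least-squares solution and the flag
#' is `FALSE`, so downstream reports make no uniqueness claim.
#'
#' @param conditionals Named list: fragment name -> observed conditional
#'   fragment MID at shift `j` (numeric, length `n_frag + 1`).
#' @param j Precursor mass shift the candidates explain.
#' @param candidates An `isotopomer_set` (or list of atom-label vectors).
#' @param fragments Named list of [fragment_def()] matching `conditionals`.
#' @param element Tracer element for labels.
#' @return An `isotopomer_fit`: list with `weights` (named, sums to 1),
#'   `residual` (L2 norm of `A w - b`), `rank`, `identifiable`, `shift`,
#'   `candidates`.
#' @examples
#' lib <- gsh_pathway_library("C")
#' glu <- lib$glutamate
#' resolve_isotopomer_fractions(
#'   list(Frag_1 = c(0, 0.6, 0.4, 0, 0)), j = 2,
#'   candidates = enumerate_isotopomers(glu, 2),
#'   fragments = glu$fragments["Frag_1"]
#' )
#' @export
resolve_isotopomer_fractions <- function(conditionals, j, candidates, fragments,
                                         element = "C") {
  if (length(candidates) == 0L) abort("Empty candidate set.")
  if (length(conditionals) == 0L) abort("No fragment conditionals supplied.")
  if (is.null(names(conditionals)) ||
      !all(names(conditionals) %in% names(fragments))) {
    abort("`conditionals` must be named by fragments present in `fragments`.")
  }
  labels <- vapply(candidates, isotopomer_label, character(1), element = element)
  ncand <- length(candidates)
  A_blocks <- list()
  b_blocks <- list()
  for (fname in names(conditionals)) {
    frag <- fragments[[fname]]
    nf <- length(frag$atoms)
    b <- as.numeric(conditionals[[fname]])
    if (length(b) != nf + 1L) {
      abort(sprintf("Conditional for fragment '%s' has length %d, expected %d.",
                    fname, length(b), nf + 1L))
    }
    A <- matrix(0, nf + 1L, ncand)
    for (s in seq_len(ncand)) {
      k <- predict_fragment_shift(candidates[[s]], frag)
      A[k + 1L, s] <- 1
    }
    A_blocks[[fname]] <- A
    b_blocks[[fname]] <- b
  }
  A <- do.call(rbind, A_blocks)
  b <- unlist(b_blocks, use.names = FALSE)
  r <- qr(rbind(A, rep(1, ncand)))$rank
  identifiable <- r >= ncand
  w <- solve_simplex_lsq(A, b)
  residual <- sqrt(sum((A %*% w - b)^2))
  structure(
    list(weights = stats::setNames(w, labels), residual = residual,
         rank = r, identifiable = identifiable, shift = j,
         candidates = candidates, element = element),
    class = "isotopomer_fit"
  )
}

# min ||A w - b||^2  s.t.  w >= 0, sum(w) = 1.
# Quadratic program; A'A is regularized by a vanishing ridge when (and only
# when) it is singular, in which case the caller has already flagged the fit
# unidentifiable.
solve_simplex_lsq <- function(A, b) {
  ncand <- ncol(A)
  if (ncand == 1L) return(1)
  D <- crossprod(A)
  d <- crossprod(A, b)
  Amat <- cbind(rep(1, ncand), diag(ncand))
  bvec <- c(1, rep(0, ncand))
  sol <- tryCatch(
    quadprog::solve.QP(D, d, Amat, bvec, meq = 1),
    error = function(e) NULL
  )
  if (is.null(sol)) {
    sol <- quadprog::solve.QP(D + diag(1e-10, ncand), d, Amat, bvec, meq = 1)
  }
  w <- pmax(sol$solution, 0)
  w / sum(w)
}

#' @export
print.isotopomer_fit <- function(x, ...) {
  cat(sprintf("<isotopomer_fit> precursor shift %d, %d candidate(s), %s\n",
              x$shift, length(x$weights),
              if (x$identifiable) "identifiable" else "NOT identifiable"))
  print(round(x$weights, 6))
  cat(sprintf("residual %.3g, design rank %d\n", x$residual, x$rank))
  invisible(x)
}

#' Resolve isotopomers across a corrected study
#'
#' For every (sample, metabolite) with declared candidate isotopomers and
#' measured fragment spectra at those precursor shifts, runs
#' [resolve_isotopomer_fractions()] jointly over all declared fragments.
#'
#' @param corrected Output of [correct_study()].
#' @param library The `metabolite_library`.
#' @return A tibble with one row per (sample, metabolite, shift, isotopomer):
#'   columns `isotopomer`, `weight`, `fraction` (weight times the precursor
#'   isotopologue fraction), `identifiable`, `residual`.
#' @export
resolve_study <- function(corrected, library) {
  meta_cols <- intersect(c("group", "control"), names(corrected))
  element <- library[[1]]$tracer_element
  frag_rows <- dplyr::filter(corrected, !is.na(.data$fragment),
                             !is.na(.data$fraction))
  if (nrow(frag_rows) == 0L) return(tibble())
  keys <- dplyr::distinct(frag_rows, dplyr::across(dplyr::all_of(
    c("sample", meta_cols, "metabolite"))))
  purrr::pmap_dfr(keys, function(...) {
    key <- list(...)
    met <- library[[key$metabolite]]
    shifts <- names(met$isotopomers)
    if (is.null(shifts) || length(shifts) == 0L) return(tibble())
    sub <- dplyr::filter(frag_rows, .data$sample == key$sample,
                         .data$metabolite == key$metabolite)
    prec <- dplyr::filter(corrected, .data$sample == key$sample,
                          .data$metabolite == key$metabolite,
                          is.na(.data$fragment), !is.na(.data$fraction))
    purrr::map_dfr(as.integer(shifts), function(j) {
      at_j <- dplyr::filter(sub, .data$precursor_index == j)
      if (nrow(at_j) == 0L) return(tibble())
      conditionals <- at_j |>
        dplyr::group_by(.data$fragment) |>
        dplyr::arrange(.data$iso_index, .by_group = TRUE) |>
        dplyr::summarise(mid = list(.data$fraction), .groups = "drop")
      cond_list <- stats::setNames(conditionals$mid, conditionals$fragment)
      fit <- resolve_isotopomer_fractions(
        cond_list, j, enumerate_isotopomers(met, j),
        fragments = met$fragments, element = element)
      prec_frac <- prec$fraction[prec$iso_index == j]
      prec_frac <- if (length(prec_frac) == 1L) prec_frac else NA_real_
      tibble(
        !!!key,
        shift = j,
        isotopomer = names(fit$weights),
        weight = unname(fit$weights),
        fraction = unname(fit$weights) * prec_frac,
        identifiable = fit$identifiable,
        residual = fit$residual
      )
    })
  })
}

#' Isotopomer-resolved MID report
#'
#' Splits each precursor isotopologue fraction into named positional
#' isotopomer fractions (tandem MID report): for shifts with a resolved fit
#' the rows are `weight * M_j`; unresolved shifts are reported as a single
#' isotopologue row. Conservation holds by construction: isotopomer rows at
#' shift `j` sum to `M_j`.
#'
#' @param solutions Output of [resolve_study()].
#' @param corrected Output of [correct_study()] (for the precursor MIDs).
#' @return A tibble: `sample`, metadata, `metabolite`, `shift`, `isotopomer`,
#'   `fraction`, `identifiable`, `residual`.
#' @export
tandem_mid_report <- function(solutions, corrected) {
  meta_cols <- intersect(c("group", "control"), names(corrected))
  prec <- corrected |>
    dplyr::filter(is.na(.data$fragment), !is.na(.data$fraction)) |>
    dplyr::select(dplyr::all_of(c("sample", meta_cols, "metabolite",
                                  "iso_index", "fraction"))) |>
    dplyr::rename(shift = "iso_index")
  resolved_keys <- if (nrow(solutions) > 0L) {
    dplyr::distinct(solutions, .data$sample, .data$metabolite, .data$shift)
  } else {
    tibble(sample = character(0), metabolite = character(0),
           shift = integer(0))
  }
  unresolved <- prec |>
    dplyr::anti_join(resolved_keys, by = c("sample", "metabolite", "shift")) |>
    dplyr::filter(.data$fraction > 0) |>
    dplyr::mutate(isotopomer = paste0("M+", .data$shift),
                  identifiable = NA, residual = NA_real_)
  resolved <- if (nrow(solutions) > 0L) {
    dplyr::select(solutions, dplyr::all_of(c(
      "sample", intersect(meta_cols, names(solutions)), "metabolite", "shift",
      "isotopomer", "fraction", "identifiable", "residual")))
  } else {
    NULL
  }
  dplyr::bind_rows(resolved, unresolved) |>
    dplyr::arrange(.data$sample, .data$metabolite, .data$shift)
}
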