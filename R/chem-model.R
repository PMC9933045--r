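#' @importFrom rlang abort warn inform %||% .data
#' @importFrom tibble tibble as_tibble
NULL

# Elements the formula parser accepts, in Hill order (C, H, then alphabetical).
.known_elements <- c("C", "H", "N", "O", "P", "S")

# Natural heavy-isotope abundances used throughout. For the tracer element the
# relevant number is the probability that an unlabeled position carries the
# heavy isotope (13C, 15N). For non-tracer elements (low-resolution mode) each
# entry is the single-atom distribution over nominal mass shifts 0, 1, 2, ...
.natural_abundance_default <- c(C = 0.0107, N = 0.00364)

.isotope_patterns <- list(
  C = c(1 - 0.0107, 0.0107),
  H = c(1 - 0.000115, 0.000115),
  N = c(1 - 0.00364, 0.00364),
  O = c(1 - 0.00038 - 0.00205, 0.00038, 0.00205),
  P = 1,
  S = c(1 - 0.0075 - 0.0425 - 0.0001, 0.0075, 0.0425, 0, 0.0001)
)

#' Parse a chemical formula
#'
#' Parses a Hill-notation formula string (e.g. `"C5H9NO4"`) into a named
#' integer vector of element counts. Only C, H, N, O, P and S are accepted;
#' these cover the polar metabolites of central carbon and glutathione
#' metabolism.
#'
#' @param text A formula string such as `"C10H17N3O6S"`.
#' @return A named integer vector of class `elemental_formula`.
#' @examples
#' parse_formula("C5H9NO4")   # glutamate
#' parse_formula("C10H17N3O6S") # glutathione
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text)) {
    abort("`text` must be a single non-empty formula string.")
  }
  tokens <- gregexpr("[A-Z][a-z]?[0-9]*", text)[[1]]
  matched <- regmatches(text, gregexpr("[A-Z][a-z]?[0-9]*", text))[[1]]
  if (paste(matched, collapse = "") != text) {
    leftover <- sub(paste(gsub("([A-Za-z0-9])", "\\1", matched), collapse = ""), "", text, fixed = TRUE)
    abort(sprintf("Malformed formula '%s': unparseable token near '%s'.", text, leftover))
  }
  counts <- integer(0)
  for (tok in matched) {
    sym <- sub("[0-9]*$", "", tok)
    num <- sub("^[A-Za-z]+", "", tok)
    if (!sym %in% .known_elements) {
      abort(sprintf("Unknown element symbol '%s' in formula '%s'.", sym, text))
    }
    n <- if (nzchar(num)) as.integer(num) else 1L
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + n
  }
  new_elemental_formula(counts)
}

new_elemental_formula <- function(counts) {
  counts <- counts[counts > 0L]
  if (length(counts) == 0L) abort("A formula must contain at least one atom.")
  ord <- c(intersect(c("C", "H"), names(counts)),
           sort(setdiff(names(counts), c("C", "H"))))
  structure(counts[ord], class = "elemental_formula")
}

#' @export
format.elemental_formula <- function(x, ...) {
  paste0(names(x), ifelse(unclass(x) > 1L, unclass(x), ""), collapse = "")
}

#' @export
print.elemental_formula <- function(x, ...) {
  cat("<elemental_formula> ", format(x), "\n", sep = "")
  invisible(x)
}

#' @export
as.character.elemental_formula <- function(x, ...) format(x)

#' Tracer specification
#'
#' Describes the isotopic tracer: which element is traced, the isotopic purity
#' of the labeled substrate (probability that a nominally labeled atom is
#' actually heavy) and the natural abundance of the heavy isotope at unlabeled
#' positions.
#'
#' @param element `"C"` (13C tracing) or `"N"` (15N tracing).
#' @param purity Probability in (0, 1] that a nominally labeled tracer atom is
#'   heavy. Commercial D-13C6-glucose is typically 0.99, L-15N2-glutamine 0.98.
#' @param natural_abundance Probability in \[0, 1\] of the heavy isotope at an
#'   unlabeled position. Defaults to the standard reference value for the
#'   element (13C 0.0107, 15N 0.00364).
#' @return An object of class `tracer_spec`.
#' @examples
#' tracer_spec("C", purity = 0.99)
#' tracer_spec("N", purity = 0.98)
#' @export
tracer_spec <- function(element = c("C", "N"), purity = 1,
                        natural_abundance = NULL) {
  element <- match.arg(element)
  natural_abundance <- natural_abundance %||% .natural_abundance_default[[element]]
  if (!is.numeric(purity) || length(purity) != 1L || purity < 0 || purity > 1) {
    abort("`purity` must be a single probability in [0, 1].")
  }
  if (!is.numeric(natural_abundance) || natural_abundance < 0 || natural_abundance > 1) {
    abort("`natural_abundance` must be a probability in [0, 1].")
  }
  structure(
    list(element = element, purity = purity,
         natural_abundance = natural_abundance),
    class = "tracer_spec"
  )
}

#' @export
print.tracer_spec <- function(x, ...) {
  cat(sprintf("<tracer_spec> %s tracer, purity %.4g, natural abundance %.4g\n",
              x$element, x$purity, x$natural_abundance))
  invisible(x)
}

#' Define a metabolite for tracer analysis
#'
#' A metabolite definition carries the elemental formula, the traced element
#' and an ordered set of tracer-atom labels (`c1..cn` for carbon, `n1..nn` for
#' nitrogen). Fragments and declared positional-isotopomer candidates hang off
#' the definition.
#'
#' @param name Metabolite name used in peak tables.
#' @param formula An `elemental_formula` or a formula string.
#' @param tracer_element Element being traced, `"C"` or `"N"`.
#' @param atoms Optional explicit atom labels; defaults to
#'   `c1..cn` / `n1..nn` where n is the tracer-element count of the formula.
#' @param fragments Named list of [fragment_def()] objects.
#' @param isotopomers Named list keyed by precursor mass shift (as character),
#'   each a list of candidate labeled-position subsets (character vectors of
#'   atom labels).
#' @return An object of class `metabolite_def`.
#' @examples
#' metabolite_def("glutamate", "C5H9NO4", "C")
#' @export
metabolite_def <- function(name, formula, tracer_element = c("C", "N"),
                           atoms = NULL, fragments = list(),
                           isotopomers = list()) {
  tracer_element <- match.arg(tracer_element)
  if (is.character(formula)) formula <- parse_formula(formula)
  n <- tracer_atom_count_formula(formula, tracer_element)
  if (n == 0L) {
    abort(sprintf(
      "Metabolite '%s' has no %s atoms and cannot be traced with a %s tracer.",
      name, tracer_element, tracer_element))
  }
  atoms <- atoms %||% paste0(tolower(tracer_element), seq_len(n))
  if (length(atoms) != n) {
    abort(sprintf(
      "Metabolite '%s': %d atom labels supplied but formula has %d %s atoms.",
      name, length(atoms), n, tracer_element))
  }
  if (anyDuplicated(atoms)) abort(sprintf("Metabolite '%s': atom labels must be unique.", name))
  met <- structure(
    list(name = name, formula = formula, tracer_element = tracer_element,
         atoms = atoms, n = n, fragments = list(), isotopomers = isotopomers),
    class = "metabolite_def"
  )
  for (frag in fragments) met <- add_fragment(met, frag)
  met
}

tracer_atom_count_formula <- function(formula, element) {
  if (element %in% names(formula)) as.integer(formula[[element]]) else 0L
}

#' Number of tracer atoms in a metabolite
#'
#' @param met A [metabolite_def()].
#' @param tracer A [tracer_spec()] (or an element symbol).
#' @return Integer count of tracer-element atoms. Errors if the metabolite
#'   contains none (it cannot be traced).
#' @examples
#' glu <- metabolite_def("glutamate", "C5H9NO4", "C")
#' tracer_atom_count(glu, tracer_spec("C"))
#' @export
tracer_atom_count <- function(met, tracer) {
  element <- if (inherits(tracer, "tracer_spec")) tracer$element else tracer
  n <- tracer_atom_count_formula(met$formula, element)
  if (n == 0L) {
    abort(sprintf("Metabolite '%s' contains no %s atoms: cannot be traced.",
                  met$name, element))
  }
  n
}

#' Define an MS2 fragment by its retained tracer atoms
#'
#' @param name Fragment name used in peak tables.
#' @param atoms Character vector of parent tracer-atom labels retained in the
#'   fragment (e.g. `c("c2","c3","c4","c5")`).
#' @param formula Optional fragment `elemental_formula` (or string) for
#'   low-resolution correction.
#' @param partition_group Optional string; fragments sharing a group label are
#'   declared to tile the parent's tracer atoms (a moiety partition), enabling
#'   moiety-weighted enrichment.
#' @return An object of class `fragment_def` (unvalidated until attached to a
#'   parent with [add_fragment()] / [validate_fragment()]).
#' @export
fragment_def <- function(name, atoms, formula = NULL, partition_group = NULL) {
  if (length(atoms) == 0L) abort(sprintf("Fragment '%s': atom subset must be non-empty.", name))
  if (anyDuplicated(atoms)) abort(sprintf("Fragment '%s': duplicated atom labels.", name))
  if (is.character(formula)) formula <- parse_formula(formula)
  structure(
    list(name = name, atoms = atoms, formula = formula,
         partition_group = partition_group, parent = NULL, complement = NULL),
    class = "fragment_def"
  )
}

#' Validate a fragment against its parent metabolite
#'
#' Checks that the fragment's atom subset is contained in the parent's tracer
#' atoms and computes the complement subset (atoms lost on fragmentation).
#'
#' @param frag A [fragment_def()].
#' @param parent The parent [metabolite_def()].
#' @return The validated fragment with `parent` and `complement` filled in.
#' @export
validate_fragment <- function(frag, parent) {
  extra <- setdiff(frag$atoms, parent$atoms)
  if (length(extra) > 0L) {
    abort(sprintf(
      "Fragment '%s' of '%s' references atoms not in the parent: %s.",
      frag$name, parent$name, paste(extra, collapse = ", ")))
  }
  frag$parent <- parent$name
  frag$complement <- setdiff(parent$atoms, frag$atoms)
  frag
}

#' Attach a fragment to a metabolite definition
#'
#' @param met A [metabolite_def()].
#' @param frag A [fragment_def()]; validated on attachment.
#' @return The metabolite with the fragment registered.
#' @export
add_fragment <- function(met, frag) {
  frag <- validate_fragment(frag, met)
  met$fragments[[frag$name]] <- frag
  met
}

#' Fragments forming a moiety partition
#'
#' Returns the fragments of `met` in partition group `group`, after checking
#' that their atom subsets are disjoint and jointly cover all tracer atoms
#' (e.g. glutathione F1 + F2 tile its 10 carbons).
#'
#' @param met A [metabolite_def()].
#' @param group Partition group label; defaults to the only declared group.
#' @return Named list of fragments.
#' @export
moiety_partition <- function(met, group = NULL) {
  groups <- purrr::compact(purrr::map(met$fragments, "partition_group"))
  if (length(groups) == 0L) {
    abort(sprintf(
      "Metabolite '%s' declares no moiety partition; set `partition_group` on its fragments.",
      met$name))
  }
  group <- group %||% unique(unlist(groups))[1]
  frags <- purrr::keep(met$fragments, ~ identical(.x$partition_group, group))
  atoms <- unlist(purrr::map(frags, "atoms"))
  if (anyDuplicated(atoms) || !setequal(atoms, met$atoms)) {
    abort(sprintf(
      "Fragments in partition '%s' of '%s' must tile the tracer atoms disjointly.",
      group, met$name))
  }
  frags
}

#' @export
print.metabolite_def <- function(x, ...) {
  cat(sprintf("<metabolite_def> %s (%s), %d %s tracer atoms", x$name,
              format(x$formula), x$n, x$tracer_element))
  if (length(x$fragments)) {
    cat(sprintf("; fragments: %s", paste(names(x$fragments), collapse = ", ")))
  }
  cat("\n")
  invisible(x)
}

#' Built-in glutathione-pathway metabolite library
#'
#' Definitions for the glutamate -> GSH -> GSSG network and its precursor
#' amino acids, with fragment atom maps and declared positional-isotopomer
#' candidates:
#'
#' * glutamate with fragments `Frag_1` (c2-c5) and `Frag_2` (c4-c5) and the
#'   two first-turn TCA candidates for M+2, 1,2-13C2 (PDH entry) and
#'   3,4-13C2 (pyruvate carboxylase entry);
#' * glutathione with moiety fragments `F1` (glutamate moiety, c1-c5) and
#'   `F2` (glycine-cysteine moiety, c6-c10) forming a partition, and three
#'   M+2 candidates (13C2 on the glutamate moiety, 13C2-glycine, one atom on
#'   each moiety);
#' * GSSG as a distinct metabolite (the GSH disulfide dimer: 20 C / 6 N);
#' * serine, glycine, cysteine and ketoglutarate.
#'
#' With `tracer_element = "N"` the same network is defined over nitrogen
#' atoms (glutamate 1 N; glutathione 3 N, one per amino-acid moiety).
#'
#' @param tracer_element `"C"` or `"N"`.
#' @return Named list of [metabolite_def()] objects (class
#'   `metabolite_library`).
#' @export
gsh_pathway_library <- function(tracer_element = c("C", "N")) {
  tracer_element <- match.arg(tracer_element)
  lib <- if (tracer_element == "C") {
    list(
      glutamate = metabolite_def(
        "glutamate", "C5H9NO4", "C",
        fragments = list(
          fragment_def("Frag_1", c("c2", "c3", "c4", "c5"), formula = "C4H8NO2"),
          fragment_def("Frag_2", c("c4", "c5"), formula = "C2H4NO")
        ),
        isotopomers = list(
          `2` = list(c("c1", "c2"), c("c3", "c4"))
        )
      ),
      ketoglutarate = metabolite_def("ketoglutarate", "C5H6O5", "C"),
      serine = metabolite_def("serine", "C3H7NO3", "C"),
      glycine = metabolite_def("glycine", "C2H5NO2", "C"),
      cysteine = metabolite_def("cysteine", "C3H7NO2S", "C"),
      glutathione = metabolite_def(
        "glutathione", "C10H17N3O6S", "C",
        fragments = list(
          fragment_def("F1", paste0("c", 1:5), formula = "C5H8NO3",
                       partition_group = "moieties"),
          fragment_def("F2", paste0("c", 6:10), formula = "C5H9N2O3S",
                       partition_group = "moieties")
        ),
        isotopomers = list(
          `2` = list(c("c1", "c2"), c("c9", "c10"), c("c1", "c9"))
        )
      ),
      gssg = metabolite_def("gssg", "C20H32N6O12S2", "C")
    )
  } else {
    list(
      glutamate = metabolite_def("glutamate", "C5H9NO4", "N"),
      serine = metabolite_def("serine", "C3H7NO3", "N"),
      glycine = metabolite_def("glycine", "C2H5NO2", "N"),
      cysteine = metabolite_def("cysteine", "C3H7NO2S", "N"),
      glutathione = metabolite_def(
        "glutathione", "C10H17N3O6S", "N",
        fragments = list(
          fragment_def("F1", "n1", partition_group = "moieties"),
          fragment_def("F2", c("n2", "n3"), partition_group = "moieties")
        )
      ),
      gssg = metabolite_def("gssg", "C20H32N6O12S2", "N")
    )
  }
  structure(lib, class = "metabolite_library", tracer_element = tracer_element)
}

#' @export
print.metabolite_library <- function(x, ...) {
  cat(sprintf("<metabolite_library> %d metabolites (%s tracer): %s\n",
              length(x), attr(x, "tracer_element"),
              paste(names(x), collapse = ", ")))
  invisible(x)
}

#' Read a metabolite/fragment configuration from YAML
#'
#' The schema mirrors [gsh_pathway_library()]: a top-level `tracer_element`,
#' and a `metabolites` map whose entries carry `formula`, optional `atoms`,
#' optional `fragments` (each with `atoms`, optional `formula`,
#' `partition_group`) and optional `isotopomers` (map from precursor shift to
#' a list of atom-label vectors). Validation errors name the offending
#' metabolite or fragment.
#'
#' @param path Path to a YAML file.
#' @return A `metabolite_library`.
#' @export
read_metabolite_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file '%s' does not exist.", path))
  cfg <- yaml::read_yaml(path)
  tracer_element <- cfg$tracer_element %||% "C"
  if (is.null(cfg$metabolites) || !length(cfg$metabolites)) {
    abort(sprintf("Config '%s': no `metabolites` section.", path))
  }
  lib <- purrr::imap(cfg$metabolites, function(m, nm) {
    if (is.null(m$formula)) {
      abort(sprintf("Config '%s': metabolite '%s' lacks a formula.", path, nm))
    }
    frags <- purrr::imap(m$fragments %||% list(), function(fr, fnm) {
      if (is.null(fr$atoms)) {
        abort(sprintf("Config '%s': fragment '%s' of '%s' lacks `atoms`.",
                      path, fnm, nm))
      }
      fragment_def(fnm, unlist(fr$atoms), formula = fr$formula,
                   partition_group = fr$partition_group)
    })
    isos <- purrr::map(m$isotopomers %||% list(), function(set) {
      purrr::map(set, unlist)
    })
    metabolite_def(nm, m$formula, tracer_element,
                   atoms = if (!is.null(m$atoms)) unlist(m$atoms),
                   fragments = unname(frags), isotopomers = isos)
  })
  structure(lib, class = "metabolite_library", tracer_element = tracer_element)
}
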