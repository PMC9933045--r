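#' Simulation parameters for the glutathione tracing study
#'
#' Defines the ground-truth labeling state and measurement model for a
#' synthetic tracer experiment on the glutamate -> GSH -> GSSG network fed
#' with 13C6-glucose (or 15N2-glutamine).
#'
#' The two presets encode the study conditions the generator emulates:
#'
#' * `"healthy"`: glutamate pool 35% first-turn M+2 (split `phi = 0.6`
#'   between 1,2-13C2 via PDH and 3,4-13C2 via pyruvate carboxylase) plus
#'   46% uniformly labeled M+5 from multi-round turnover, giving a mean
#'   enrichment of 0.60; ketoglutarate analogous at 0.62; serine 0.11,
#'   glycine 0.07, cysteine unlabeled; de novo GSH fraction `f_syn = 0.67`
#'   (so GSH ME is about 0.21); oxidized share 0.10. In 15N mode glutamate
#'   is labeled at 0.23, serine at 0.05, glycine not at all.
#' * `"rotenone"`: reduced TCA entry (M+2 0.25, M+5 0.33, `phi = 0.5`),
#'   reduced de novo synthesis (`f_syn = 0.45`), increased oxidation
#'   (oxidized share 0.30) and a smaller total glutathione pool.
#'
#' @param preset `"healthy"` or `"rotenone"`.
#' @param tracer_element `"C"` or `"N"`.
#' @param ... Named overrides of any field below.
#'
#' @section Fields:
#' * `phi`: share of glutamate first-turn M+2 carried by the 1,2-isotopomer
#'   (PDH entry) vs 3,4 (PC entry).
#' * `glu_m2`, `glu_m5`, `akg_m2`, `akg_m5`: glutamate / ketoglutarate pool
#'   fractions at first-turn M+2 and uniformly labeled M+n.
#' * `ser_labeled`, `gly_labeled`: fully 13C-labeled fractions of serine and
#'   glycine.
#' * `glu_n15`, `ser_n15`: 15N-labeled fractions (15N mode).
#' * `f_syn`: de novo fraction of the GSH pool (newly assembled from the
#'   current precursor pools; the remainder is pre-existing, unlabeled).
#' * `oxidized_share`: share of total glutathione (GSH equivalents) oxidized
#'   to GSSG.
#' * `abundance`: named base peak-area scale per metabolite (area units per
#'   µg protein); glutathione's entry is the total pool, split between GSH
#'   and GSSG by `oxidized_share`.
#' * `noise_cv`: coefficient of variation of multiplicative lognormal
#'   measurement noise on peak areas.
#' * `protein_mean`, `protein_cv`: per-sample protein content (µg), normal
#'   truncated at zero.
#' * `replicates`: labeled replicates per group.
#' * `purity`: tracer isotopic purity (0.99 for 13C6-glucose, 0.98 for
#'   15N2-glutamine).
#' @return A `simulation_params` list.
#' @export
simulation_params <- function(preset = c("healthy", "rotenone"),
                              tracer_element = c("C", "N"), ...) {
  preset <- match.arg(preset)
  tracer_element <- match.arg(tracer_element)
  p <- list(
    tracer_element = tracer_element,
    purity = if (tracer_element == "C") 0.99 else 0.98,
    phi = 0.6,
    glu_m2 = 0.35, glu_m5 = 0.46,
    akg_m2 = 0.35, akg_m5 = 0.48,
    ser_labeled = 0.11, gly_labeled = 0.07,
    glu_n15 = 0.23, ser_n15 = 0.05,
    f_syn = 0.67,
    oxidized_share = 0.10,
    abundance = c(glutamate = 8e5, ketoglutarate = 3e5, serine = 4e5,
                  glycine = 5e5, cysteine = 2e5, glutathione = 1e6),
    noise_cv = 0.1,
    protein_mean = 38, protein_cv = 0.15,
    replicates = 5
  )
  if (preset == "rotenone") {
    p$phi <- 0.5
    p$glu_m2 <- 0.25; p$glu_m5 <- 0.33
    p$akg_m2 <- 0.25; p$akg_m5 <- 0.35
    p$f_syn <- 0.45
    p$oxidized_share <- 0.30
    p$glu_n15 <- 0.20
    p$abundance[["glutathione"]] <- 7e5
  }
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad) > 0L) {
    abort(sprintf("Unknown simulation parameter(s): %s.", paste(bad, collapse = ", ")))
  }
  p[names(over)] <- over
  frac_fields <- c("purity", "phi", "glu_m2", "glu_m5", "akg_m2", "akg_m5",
                   "ser_labeled", "gly_labeled", "glu_n15", "ser_n15",
                   "f_syn", "oxidized_share")
  for (f in frac_fields) {
    if (p[[f]] < 0 || p[[f]] > 1) abort(sprintf("`%s` must be in [0, 1].", f))
  }
  if (p$glu_m2 + p$glu_m5 > 1 || p$akg_m2 + p$akg_m5 > 1) {
    abort("M+2 and M+n pool fractions must sum to at most 1.")
  }
  if (p$noise_cv < 0 || p$protein_cv < 0) abort("CVs must be >= 0.")
  if (p$replicates < 1) abort("`replicates` must be >= 1.")
  p$preset <- preset
  structure(p, class = "simulation_params")
}

# --- positional isotopomer distributions ------------------------------------
# Represented as a named numeric vector: names are "+"-joined atom labels
# ("(none)" = unlabeled), values are fractions summing to 1.

# "(none)" marks the unlabeled isotopomer: the empty string cannot be used as
# a name because R's character subsetting never matches "".
iso_key <- function(atoms) {
  if (length(atoms) == 0L) "(none)" else paste(sort(atoms), collapse = "+")
}
unlabeled_dist <- function() stats::setNames(1, "(none)")
iso_atoms <- function(key) {
  if (key == "(none)" || !nzchar(key)) character(0)
  else strsplit(key, "+", fixed = TRUE)[[1]]
}

iso_dist <- function(keys, fractions) {
  stopifnot(abs(sum(fractions) - 1) < 1e-9)
  out <- tapply(fractions, keys, sum)
  stats::setNames(as.numeric(out), names(out))
}

# product distribution of independent moieties (atom sets are disjoint)
iso_product <- function(d1, d2) {
  keys <- outer(names(d1), names(d2), function(a, b) {
    vapply(seq_along(a), function(i) iso_key(c(iso_atoms(a[i]), iso_atoms(b[i]))),
           character(1))
  })
  iso_dist(as.vector(keys), as.vector(outer(unname(d1), unname(d2))))
}

iso_mix <- function(dists, weights) {
  stopifnot(abs(sum(weights) - 1) < 1e-9)
  all_keys <- unique(unlist(lapply(dists, names)))
  out <- stats::setNames(numeric(length(all_keys)), all_keys)
  for (i in seq_along(dists)) {
    out[names(dists[[i]])] <- out[names(dists[[i]])] + weights[i] * dists[[i]]
  }
  out
}

iso_to_mid <- function(dist, n) {
  mid <- numeric(n + 1L)
  sizes <- vapply(names(dist), function(k) length(iso_atoms(k)), integer(1))
  for (i in seq_along(dist)) mid[sizes[i] + 1L] <- mid[sizes[i] + 1L] + dist[i]
  mid
}

# conditional fragment MIDs: list keyed by precursor shift j (character)
iso_fragment_conditionals <- function(dist, frag, n) {
  sizes <- vapply(names(dist), function(k) length(iso_atoms(k)), integer(1))
  shifts <- vapply(names(dist), function(k) predict_fragment_shift(iso_atoms(k), frag),
                   integer(1))
  nf <- length(frag$atoms)
  out <- list()
  for (j in sort(unique(sizes))) {
    sel <- sizes == j
    mass <- sum(dist[sel])
    if (mass <= 1e-15) next
    cond <- numeric(nf + 1L)
    for (i in which(sel)) cond[shifts[i] + 1L] <- cond[shifts[i] + 1L] + dist[i]
    out[[as.character(j)]] <- cond / mass
  }
  out
}

#' Generate the ground-truth labeling state
#'
#' Builds per-metabolite positional isotopomer distributions for the
#' glutathione network under the given parameters, and derives from them the
#' true MIDs and true conditional fragment MIDs:
#'
#' * glutamate: unlabeled + first-turn M+2 split `phi : (1 - phi)` between
#'   1,2- and 3,4-13C2 + uniformly labeled M+5 (ketoglutarate analogous);
#' * serine and glycine: fully labeled fractions; cysteine always unlabeled;
#' * GSH: a mixture of `f_syn` de novo molecules — glutamate moiety drawn
#'   from the current glutamate distribution, glycine carbons from the
#'   glycine distribution, cysteine carbons unlabeled — and `1 - f_syn`
#'   pre-existing unlabeled molecules;
#' * GSSG: the GSH disulfide dimer; its MID is the self-convolution of the
#'   GSH MID;
#' * 15N mode: glutamate's single nitrogen labeled at `glu_n15`, propagating
#'   only into the GSH glutamate moiety (F1); the glycine-cysteine moiety
#'   nitrogens stay unlabeled.
#'
#' @param params A [simulation_params()].
#' @param library A `metabolite_library`; defaults to
#'   [gsh_pathway_library()] for the params' tracer element.
#' @return A `ground_truth`: named list per metabolite with elements
#'   `isotopomers`, `mid`, `me`, `conditionals` (fragment -> shift ->
#'   conditional MID).
#' @export
generate_ground_truth <- function(params, library = NULL) {
  library <- library %||% gsh_pathway_library(params$tracer_element)
  el <- params$tracer_element
  dists <- if (el == "C") {
    glu <- iso_mix(
      list(unlabeled_dist(), c(`c1+c2` = 1), c(`c3+c4` = 1),
           stats::setNames(1, iso_key(paste0("c", 1:5)))),
      c(1 - params$glu_m2 - params$glu_m5, params$glu_m2 * params$phi,
        params$glu_m2 * (1 - params$phi), params$glu_m5))
    akg <- iso_mix(
      list(unlabeled_dist(), c(`c1+c2` = 1), c(`c3+c4` = 1),
           stats::setNames(1, iso_key(paste0("c", 1:5)))),
      c(1 - params$akg_m2 - params$akg_m5, params$akg_m2 * params$phi,
        params$akg_m2 * (1 - params$phi), params$akg_m5))
    ser <- iso_mix(list(unlabeled_dist(), c(`c1+c2+c3` = 1)),
                   c(1 - params$ser_labeled, params$ser_labeled))
    gly <- iso_mix(list(unlabeled_dist(), c(`c1+c2` = 1)),
                   c(1 - params$gly_labeled, params$gly_labeled))
    cys <- unlabeled_dist()
    # de novo GSH: glutamate moiety c1-c5 (same labels), cysteine c6-c8
    # (unlabeled), glycine carbons c9-c10
    gly_moiety <- stats::setNames(
      unname(gly), vapply(names(gly), function(k) {
        iso_key(sub("^c2$", "c10", sub("^c1$", "c9", iso_atoms(k))))
      }, character(1)))
    de_novo <- iso_product(glu, gly_moiety)
    gsh <- iso_mix(list(de_novo, unlabeled_dist()), c(params$f_syn, 1 - params$f_syn))
    list(glutamate = glu, ketoglutarate = akg, serine = ser, glycine = gly,
         cysteine = cys, glutathione = gsh)
  } else {
    glu <- iso_mix(list(unlabeled_dist(), c(n1 = 1)),
                   c(1 - params$glu_n15, params$glu_n15))
    ser <- iso_mix(list(unlabeled_dist(), c(n1 = 1)),
                   c(1 - params$ser_n15, params$ser_n15))
    gly <- unlabeled_dist()
    cys <- unlabeled_dist()
    # GSH nitrogens: n1 = glutamate moiety, n2 = cysteine, n3 = glycine
    de_novo <- glu  # n2, n3 unlabeled: product with point mass is identity
    gsh <- iso_mix(list(de_novo, unlabeled_dist()), c(params$f_syn, 1 - params$f_syn))
    list(glutamate = glu, serine = ser, glycine = gly, cysteine = cys,
         glutathione = gsh)
  }
  truth <- purrr::imap(dists, function(dist, nm) {
    met <- library[[nm]]
    mid <- iso_to_mid(dist, met$n)
    conds <- purrr::map(met$fragments, iso_fragment_conditionals,
                        dist = dist, n = met$n)
    list(isotopomers = dist, mid = mid,
         me = sum(mid * (0:met$n)) / met$n, conditionals = conds)
  })
  # GSSG: disulfide dimer of two independent GSH molecules
  gssg_n <- library$gssg$n
  gssg_mid <- conv_vec(truth$glutathione$mid, truth$glutathione$mid)
  truth$gssg <- list(isotopomers = NULL, mid = gssg_mid,
                     me = sum(gssg_mid * (0:gssg_n)) / gssg_n,
                     conditionals = list())
  structure(truth, class = "ground_truth", params = params)
}

unlabeled_params <- function(params) {
  zero <- list(glu_m2 = 0, glu_m5 = 0, akg_m2 = 0, akg_m5 = 0,
               ser_labeled = 0, gly_labeled = 0, glu_n15 = 0, ser_n15 = 0)
  params[names(zero)] <- zero
  params
}

rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

rprotein <- function(n, mean, cv) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      x <- stats::rnorm(1, mean, cv * mean)
      if (x > 0) break
    }
    out[i] <- x
  }
  out
}

#' Simulate measured peak areas from a ground truth
#'
#' Forward measurement model: the true MID of each species is pushed through
#' the combined natural-abundance and purity convolution
#' (`F_total = F_nat %*% F_purity`), scaled by the metabolite's base
#' abundance and the sample's protein content, and multiplied by per-row
#' lognormal noise at the stated CV. Fragment spectra are emitted per
#' precursor shift: the true conditional fragment MID convolved with the
#' fragment-sized forward matrix. Output is deterministic given the RNG
#' state.
#'
#' @param truth A `ground_truth`.
#' @param params A [simulation_params()].
#' @param sample_id Sample name.
#' @param group Group label.
#' @param library A `metabolite_library`.
#' @param control Logical flag carried to the output rows.
#' @param protein_ug Optional fixed protein content; drawn if `NULL`.
#' @return A long-format study tibble (columns `sample`, `group`,
#'   `protein_ug`, `control`, `metabolite`, `fragment`, `precursor_index`,
#'   `iso_index`, `area`).
#' @export
simulate_measurement <- function(truth, params, sample_id, group = "group",
                                 library = NULL, control = FALSE,
                                 protein_ug = NULL) {
  library <- library %||% gsh_pathway_library(params$tracer_element)
  tracer <- tracer_spec(params$tracer_element, purity = params$purity)
  protein_ug <- protein_ug %||% rprotein(1, params$protein_mean, params$protein_cv)
  abundance <- params$abundance
  # split the glutathione pool into GSH and GSSG (2 GSH per GSSG)
  gsh_total <- abundance[["glutathione"]]
  abundance[["glutathione"]] <- gsh_total * (1 - params$oxidized_share)
  abundance[["gssg"]] <- gsh_total * params$oxidized_share / 2
  rows <- purrr::imap_dfr(truth, function(tr, nm) {
    met <- library[[nm]]
    if (is.null(met)) return(tibble())
    scale <- abundance[[nm]] * protein_ug / params$protein_mean
    Fp <- as.matrix(correction_matrix(met$n, tracer))
    obs <- as.numeric(Fp %*% tr$mid)
    prec <- tibble(
      metabolite = nm, fragment = NA_character_,
      precursor_index = NA_integer_, iso_index = 0:met$n,
      area = scale * obs * rlnorm_cv(met$n + 1L, params$noise_cv)
    )
    frag_rows <- purrr::imap_dfr(tr$conditionals, function(conds, fname) {
      frag <- met$fragments[[fname]]
      nf <- length(frag$atoms)
      Ff <- as.matrix(correction_matrix(nf, tracer))
      purrr::imap_dfr(conds, function(cond, j_chr) {
        j <- as.integer(j_chr)
        obs_cond <- as.numeric(Ff %*% cond)
        tibble(
          metabolite = nm, fragment = fname, precursor_index = j,
          iso_index = 0:nf,
          area = scale * tr$mid[j + 1L] * obs_cond *
            rlnorm_cv(nf + 1L, params$noise_cv)
        )
      })
    })
    dplyr::bind_rows(prec, frag_rows)
  })
  dplyr::mutate(rows, sample = sample_id, group = group,
                protein_ug = protein_ug, control = control,
                .before = 1)
}

#' Generate a two-group tracer study
#'
#' Simulates the full study design: `replicates` labeled samples per group
#' under each group's own parameters, plus one unlabeled control sample per
#' group (tracer-free medium: the true labeling state is entirely unlabeled,
#' so any apparent enrichment surviving correction is an artifact).
#'
#' @param healthy A [simulation_params()] for the reference group.
#' @param perturbed A [simulation_params()] for the perturbed group.
#' @param seed Integer seed; all randomness in the study flows from it.
#' @param library Optional `metabolite_library`.
#' @return A `tracer_study` list: `areas` (long study tibble), `truth`
#'   (ground truths per group and for the controls), `params`, `seed`.
#' @examples
#' study <- generate_study(seed = 1)
#' dplyr::count(study$areas, group, control)
#' @export
generate_study <- function(healthy = simulation_params("healthy"),
                           perturbed = simulation_params("rotenone"),
                           seed = 1, library = NULL) {
  if (healthy$tracer_element != perturbed$tracer_element) {
    abort("Both groups must use the same tracer element.")
  }
  library <- library %||% gsh_pathway_library(healthy$tracer_element)
  set.seed(seed)
  groups <- list(healthy = healthy, rotenone = perturbed)
  truths <- purrr::map(groups, generate_ground_truth, library = library)
  ctrl_truths <- purrr::map(groups, function(p) {
    generate_ground_truth(unlabeled_params(p), library = library)
  })
  areas <- purrr::imap_dfr(groups, function(p, gname) {
    reps <- purrr::map_dfr(seq_len(p$replicates), function(i) {
      simulate_measurement(truths[[gname]], p,
                           sample_id = sprintf("%s_%d", gname, i),
                           group = gname, library = library)
    })
    ctrl <- simulate_measurement(ctrl_truths[[gname]], p,
                                 sample_id = sprintf("%s_ctrl", gname),
                                 group = gname, library = library,
                                 control = TRUE)
    dplyr::bind_rows(reps, ctrl)
  })
  structure(list(areas = areas, truth = truths, control_truth = ctrl_truths,
                 params = groups, seed = seed),
            class = "tracer_study")
}

#' @export
print.tracer_study <- function(x, ...) {
  cat(sprintf("<tracer_study> %d samples, %d metabolites, %s tracer (seed %d)\n",
              dplyr::n_distinct(x$areas$sample),
              dplyr::n_distinct(x$areas$metabolite),
              x$params[[1]]$tracer_element, x$seed))
  invisible(x)
}
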