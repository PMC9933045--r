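lib <- gsh_pathway_library("C")
glu <- lib$glutamate

test_that("predicted fragment shifts count retained labeled atoms", {
  expect_identical(predict_fragment_shift(c("c1", "c2"), glu$fragments$Frag_1), 1L)
  expect_identical(predict_fragment_shift(c("c3", "c4"), glu$fragments$Frag_1), 2L)
  expect_identical(predict_fragment_shift(c("c1", "c2"), glu$fragments$Frag_2), 0L)
  expect_identical(predict_fragment_shift(character(0), glu$fragments$Frag_1), 0L)
})

test_that("isotopomer enumeration honors declarations and falls back to subsets", {
  declared <- enumerate_isotopomers(glu, 2)
  expect_length(declared, 2)
  expect_identical(declared[[1]], c("c1", "c2"))
  expect_length(enumerate_isotopomers(glu, 0), 1)
  expect_identical(enumerate_isotopomers(glu, 0)[[1]], character(0))
  # no declaration at j = 3: all C(5,3) subsets, lexicographic
  all3 <- enumerate_isotopomers(glu, 3)
  expect_length(all3, choose(5, 3))
  expect_identical(all3[[1]], c("c1", "c2", "c3"))
  met4 <- metabolite_def("x", "C4H8O4", "C")
  expect_length(enumerate_isotopomers(met4, 2), 6)
  expect_error(enumerate_isotopomers(glu, 2, candidates = list("c1")),
               "shift 2")
  expect_error(enumerate_isotopomers(glu, 9), "outside")
})

test_that("tandem MIDs multiply precursor and conditional distributions", {
  t1 <- assemble_tandem_mid(normalize_mid(c(1, 0)), list(`0` = c(1, 0, 0)),
                            fragment_def("f", c("c1", "c2")))
  expect_equal(unclass(t1), rbind(c(1, 0, 0), c(0, 0, 0)), ignore_attr = TRUE)
  prec <- normalize_mid(c(0.4, 0.2, 0.3, 0.05, 0.05, 0))
  tm <- assemble_tandem_mid(prec, list(`2` = c(0, 0.6, 0.4, 0, 0)),
                            glu$fragments$Frag_1)
  expect_equal(tm[3, 2], 0.3 * 0.6)
  expect_equal(tm[3, 3], 0.3 * 0.4)
  # missing precursor rows are zero-filled and flagged
  expect_setequal(attr(tm, "missing_rows"), c(0, 1, 3, 4))
  expect_error(
    assemble_tandem_mid(prec, list(`2` = c(0.5, 0.5)), glu$fragments$Frag_1),
    "length")
})

test_that("tandem row sums reproduce the precursor MID at measured shifts", {
  withr::local_seed(11)
  for (rep in 1:10) {
    prec <- normalize_mid(random_simplex(6))
    conds <- stats::setNames(
      lapply(0:5, function(j) random_simplex(5)), as.character(0:5))
    tm <- assemble_tandem_mid(prec, conds, glu$fragments$Frag_1)
    expect_equal(unname(rowSums(unclass(tm))), as.numeric(prec),
                 tolerance = 1e-12)
    expect_equal(sum(unclass(tm)), 1, tolerance = 1e-12)
  }
})

test_that("the worked glutamate M+2 deconvolution returns the fragment ratio", {
  fit <- resolve_isotopomer_fractions(
    list(Frag_1 = c(0, 0.6, 0.4, 0, 0)), j = 2,
    candidates = enumerate_isotopomers(glu, 2),
    fragments = glu$fragments)
  expect_equal(unname(fit$weights), c(0.6, 0.4), tolerance = 1e-9)
  expect_identical(names(fit$weights), c("1,2-13C2", "3,4-13C2"))
  expect_true(fit$identifiable)
  expect_lt(fit$residual, 1e-9)
})

test_that("a single candidate gets weight one regardless of the data", {
  fit <- resolve_isotopomer_fractions(
    list(Frag_1 = c(0.2, 0.5, 0.3, 0, 0)), j = 2,
    candidates = list(c("c3", "c4")), fragments = glu$fragments)
  expect_equal(unname(fit$weights), 1)
})

test_that("impossible fragment peaks surface as high residuals", {
  # both first-turn M+2 isotopomers put at most one labeled atom into
  # Frag_2 (c4-c5): observed m+2 mass there is unexplainable
  fit <- resolve_isotopomer_fractions(
    list(Frag_2 = c(0.2, 0.3, 0.5)), j = 2,
    candidates = enumerate_isotopomers(glu, 2),
    fragments = glu$fragments)
  expect_gt(fit$residual, 0.4)
})

test_that("joint multi-fragment solves use stacked designs", {
  truth_w <- c(0.7, 0.3)
  cands <- enumerate_isotopomers(glu, 2)
  cond_f1 <- c(0, truth_w[1], truth_w[2], 0, 0)    # Frag_1: shifts 1 and 2
  cond_f2 <- c(truth_w[1], truth_w[2], 0)          # Frag_2: shifts 0 and 1
  fit <- resolve_isotopomer_fractions(
    list(Frag_1 = cond_f1, Frag_2 = cond_f2), j = 2,
    candidates = cands, fragments = glu$fragments)
  expect_equal(unname(fit$weights), truth_w, tolerance = 1e-9)
  expect_true(fit$identifiable)
})

test_that("candidates indistinguishable by the fragments are flagged", {
  # c1 and c2 both fall outside Frag_2 only; use Frag_2 alone so the two
  # single-atom candidates c1 vs c2 predict identical shifts
  fit <- resolve_isotopomer_fractions(
    list(Frag_2 = c(1, 0, 0)), j = 1,
    candidates = list("c1", "c2"), fragments = glu$fragments)
  expect_false(fit$identifiable)
  expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
})

test_that("constrained solver matches exhaustive simplex grid search", {
  withr::local_seed(23)
  cands3 <- list(c("c1", "c2"), c("c3", "c4"), c("c2", "c3"))
  for (rep in 1:8) {
    w <- random_simplex(3)
    # build b from the design and perturb slightly off the model
    A <- do.call(rbind, lapply(c("Frag_1", "Frag_2"), function(f) {
      Ab <- matrix(0, length(glu$fragments[[f]]$atoms) + 1L, 3)
      for (s in 1:3) {
        k <- predict_fragment_shift(cands3[[s]], glu$fragments[[f]])
        Ab[k + 1, s] <- 1
      }
      Ab
    }))
    b <- as.numeric(A %*% w) + stats::rnorm(nrow(A), sd = 0.01)
    fit <- resolve_isotopomer_fractions(
      list(Frag_1 = b[1:5], Frag_2 = b[6:8]), j = 2,
      candidates = cands3, fragments = glu$fragments)
    oracle <- grid_simplex_search(A, b, step = 1e-3)
    expect_lt(max(abs(unname(fit$weights) - oracle)), 2e-3)
  }
})

test_that("the tandem report conserves precursor isotopologue fractions", {
  params <- noise_free_params()
  truth <- generate_ground_truth(params, lib)
  tab <- simulate_measurement(truth, params, "s1", "g", lib, protein_ug = 38)
  corr <- correct_study(tab, lib, tracer_spec("C", purity = 0.99))
  sols <- resolve_study(corr, lib)
  rep <- tandem_mid_report(sols, corr)
  # per (metabolite, shift), isotopomer fractions sum to the precursor MID
  sums <- rep |>
    dplyr::filter(sample == "s1") |>
    dplyr::group_by(metabolite, shift) |>
    dplyr::summarise(total = sum(fraction), .groups = "drop")
  prec <- dplyr::filter(corr, is.na(fragment)) |>
    dplyr::select(metabolite, shift = iso_index, fraction)
  joined <- dplyr::inner_join(sums, prec, by = c("metabolite", "shift"))
  expect_equal(joined$total, joined$fraction, tolerance = 1e-9)
  # glutamate M+2 split recovers phi exactly in the noise-free case
  glu_rows <- dplyr::filter(sols, metabolite == "glutamate", shift == 2)
  expect_equal(glu_rows$weight[glu_rows$isotopomer == "1,2-13C2"],
               params$phi, tolerance = 1e-9)
  # PDH-dominant truth: PDH isotopomer fraction exceeds the PC one
  expect_gt(glu_rows$fraction[glu_rows$isotopomer == "1,2-13C2"],
            glu_rows$fraction[glu_rows$isotopomer == "3,4-13C2"])
})

test_that("tidy and glance expose fit internals", {
  fit <- resolve_isotopomer_fractions(
    list(Frag_1 = c(0, 0.6, 0.4, 0, 0)), j = 2,
    candidates = enumerate_isotopomers(glu, 2), fragments = glu$fragments)
  td <- tidy(fit)
  expect_identical(nrow(td), 2L)
  expect_named(td, c("isotopomer", "atoms", "weight", "shift"))
  gl <- glance(fit)
  expect_identical(gl$n_candidates, 2L)
  expect_true(gl$identifiable)
})
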