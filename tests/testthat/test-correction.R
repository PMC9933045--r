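tr_c <- tracer_spec("C", purity = 0.99)

test_that("natural-abundance matrix matches the binomial model", {
  # zero abundance: identity
  tr0 <- tracer_spec("C", natural_abundance = 0)
  expect_equal(as.matrix(natural_abundance_matrix(1, tr0)), diag(2),
               ignore_attr = TRUE)
  # n = 2, a = 0.5: columns enumerable by hand over the unlabeled positions
  tr5 <- tracer_spec("C", natural_abundance = 0.5)
  F2 <- as.matrix(natural_abundance_matrix(2, tr5))
  expect_equal(unname(F2),
               cbind(c(0.25, 0.5, 0.25), c(0, 0.5, 0.5), c(0, 0, 1)))
  # n = 5 glutamate: first subdiagonal entry from an independent binomial
  F5 <- as.matrix(natural_abundance_matrix(5, tr_c))
  expect_equal(F5[2, 1], 5 * 0.0107 * (1 - 0.0107)^4)
  expect_error(natural_abundance_matrix(0, tr_c), ">= 1")
})

test_that("purity matrix matches the binomial expansion", {
  trp1 <- tracer_spec("C", purity = 1, natural_abundance = 0)
  expect_equal(as.matrix(purity_matrix(3, trp1)), diag(4), ignore_attr = TRUE)
  P2 <- as.matrix(purity_matrix(2, tr_c))
  expect_equal(unname(P2[, 3]), c(0.0001, 0.0198, 0.9801))
  trn <- tracer_spec("N", purity = 0.98)
  expect_equal(unname(as.matrix(purity_matrix(1, trn))[, 2]), c(0.02, 0.98))
  expect_error(purity_matrix(2, tracer_spec("C", purity = 0)), "degenerate")
})

test_that("every built matrix is column-stochastic and non-negative", {
  for (n in c(1, 3, 7)) {
    for (m in list(natural_abundance_matrix(n, tr_c),
                   purity_matrix(n, tr_c),
                   correction_matrix(n, tr_c),
                   correction_matrix(n, tr_c, "low_resolution_full_formula",
                                     parse_formula("C10H17N3O6S")))) {
      M <- as.matrix(m)
      expect_true(all(M >= 0))
      expect_equal(unname(colSums(M)), rep(1, n + 1), tolerance = 1e-12)
    }
  }
})

test_that("combined matrices equal exhaustive 2^n enumeration", {
  for (n in c(1, 2, 5, 10)) {
    expect_equal(as.matrix(correction_matrix(n, tr_c)),
                 brute_force_matrix(n, 0.0107, 0.99),
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(as.matrix(natural_abundance_matrix(n, tr_c)),
                 brute_force_matrix(n, 0.0107, 1),
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(as.matrix(purity_matrix(n, tr_c)),
                 brute_force_matrix(n, 0, 0.99),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("the combined matrix applies purity first, then natural abundance", {
  # the two convolutions do not commute (the commutator is of order a*(1-p)),
  # so the composition order is a fixed contract: F_total = F_nat %*% F_pur
  A1 <- as.matrix(natural_abundance_matrix(1, tr_c))
  P1 <- as.matrix(purity_matrix(1, tr_c))
  expect_gt(max(abs(A1 %*% P1 - P1 %*% A1)), 1e-5)
  expect_lt(max(abs(A1 %*% P1 - P1 %*% A1)), 2 * 0.0107 * 0.01)
  for (n in c(1, 3)) {
    An <- as.matrix(natural_abundance_matrix(n, tr_c))
    Pn <- as.matrix(purity_matrix(n, tr_c))
    expect_equal(as.matrix(correction_matrix(n, tr_c)), An %*% Pn,
                 tolerance = 1e-14, ignore_attr = TRUE)
  }
})

test_that("low-resolution mode requires a formula and differs from high-res", {
  expect_error(correction_matrix(5, tr_c, "low_resolution_full_formula"),
               "formula")
  hi <- as.matrix(correction_matrix(5, tr_c))
  lo <- as.matrix(correction_matrix(5, tr_c, "low_resolution_full_formula",
                                    parse_formula("C5H9NO4")))
  expect_gt(max(abs(hi - lo)), 1e-4)  # O/H isotopes contribute in low-res
})

test_that("correction round-trips noise-free forward convolutions", {
  withr::local_seed(42)
  for (n in c(1, 2, 5, 10)) {
    Fm <- correction_matrix(n, tr_c)
    for (rep in 1:25) {
      x <- random_simplex(n + 1)
      m <- as.numeric(as.matrix(Fm) %*% x)
      xh <- correct_mid(m, Fm)
      expect_lt(max(abs(as.numeric(xh) - x)), 1e-8)
      expect_lt(attr(xh, "residual"), 1e-10)
    }
  }
  # the worked glutamate case: pure M+2 recovered from its convolution
  Fm <- natural_abundance_matrix(5, tr_c)
  m <- as.numeric(as.matrix(Fm) %*% c(0, 0, 1, 0, 0, 0))
  expect_lt(max(abs(as.numeric(correct_mid(m, Fm)) - c(0, 0, 1, 0, 0, 0))), 1e-8)
})

test_that("corrected vectors are normalized and inputs validated", {
  Fm <- correction_matrix(1, tr_c)
  out <- correct_mid(c(2, 2), correction_matrix(1, tracer_spec("C", purity = 1,
                                                               natural_abundance = 0)))
  expect_equal(as.numeric(out), c(0.5, 0.5))
  expect_error(correct_mid(c(0, 0), Fm), "empty signal")
  expect_error(correct_mid(c(1, NA), Fm), "non-finite")
  expect_warning(x <- correct_mid(c(100, -0.5), Fm), "Clamping")
  expect_true(all(as.numeric(x) >= 0))
  expect_equal(sum(as.numeric(x)), 1)
})

test_that("high correction residuals flag but do not error", {
  Fm <- correction_matrix(2, tr_c)
  # measured mass below M0's convolution reach: unexplainable signal
  expect_warning(out <- correct_mid(c(1, 0, 0.4), Fm, residual_threshold = 1e-6),
                 "flagged")
  expect_true(attr(out, "flagged"))
})

test_that("correct_study corrects precursors and fragments per group", {
  lib <- gsh_pathway_library("C")
  params <- noise_free_params()
  truth <- generate_ground_truth(params, lib)
  tab <- simulate_measurement(truth, params, "s1", "g", lib, protein_ug = 38)
  corr <- correct_study(tab, lib, tracer_spec("C", purity = 0.99))
  glu <- dplyr::filter(corr, metabolite == "glutamate", is.na(fragment))
  expect_equal(glu$fraction[order(glu$iso_index)], truth$glutamate$mid,
               tolerance = 1e-8)
  f1 <- dplyr::filter(corr, metabolite == "glutamate", fragment == "Frag_1",
                      precursor_index == 2L)
  expect_equal(f1$fraction[order(f1$iso_index)],
               truth$glutamate$conditionals$Frag_1[["2"]], tolerance = 1e-8)
  # undeclared metabolites dropped with a warning
  tab2 <- dplyr::mutate(tab, metabolite = ifelse(metabolite == "serine",
                                                 "mystery", metabolite))
  expect_warning(corr2 <- correct_study(tab2, lib, tracer_spec("C", purity = 0.99)),
                 "mystery")
  expect_false("mystery" %in% corr2$metabolite)
})
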