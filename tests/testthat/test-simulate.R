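test_that("ground truth encodes the configured labeling state", {
  lib <- gsh_pathway_library("C")
  # phi = 1: all first-turn M+2 on c1+c2; Frag_1 conditional at j=2 is pure m+1
  tr1 <- generate_ground_truth(noise_free_params(phi = 1), lib)
  expect_equal(tr1$glutamate$isotopomers[["c1+c2"]],
               simulation_params()$glu_m2)
  expect_false("c3+c4" %in% names(tr1$glutamate$isotopomers[
    tr1$glutamate$isotopomers > 0]))
  expect_equal(tr1$glutamate$conditionals$Frag_1[["2"]], c(0, 1, 0, 0, 0))
  # f_syn = 0: glutathione fully unlabeled
  tr0 <- generate_ground_truth(noise_free_params(f_syn = 0), lib)
  expect_equal(tr0$glutathione$mid, c(1, rep(0, 10)))
  # cysteine (3 carbons) never labeled
  tr <- generate_ground_truth(noise_free_params(), lib)
  expect_equal(tr$cysteine$mid, c(1, 0, 0, 0))
  # target enrichments of the healthy preset
  expect_equal(tr$glutamate$me, 0.60, tolerance = 1e-12)
  expect_equal(tr$ketoglutarate$me, 0.62, tolerance = 1e-12)
  expect_equal(tr$serine$me, 0.11)
  expect_equal(tr$glycine$me, 0.07)
  expect_equal(tr$glutathione$me,
               0.67 * (5 * 0.60 + 2 * 0.07) / 10, tolerance = 1e-12)
})

test_that("fragment conditionals in truth satisfy the Frag_2 impossibility", {
  for (phi in c(0, 0.3, 0.8, 1)) {
    tr <- generate_ground_truth(noise_free_params(phi = phi))
    cond <- tr$glutamate$conditionals$Frag_2[["2"]]
    expect_identical(cond[3], 0)  # no m+2 in the c4-c5 fragment at M+2
  }
})

test_that("moiety enrichments in truth tile the intact molecule exactly", {
  tr <- generate_ground_truth(noise_free_params())
  me_f1 <- local({
    conds <- tr$glutathione$conditionals$F1
    mid <- tr$glutathione$mid
    marg <- Reduce(`+`, purrr::imap(conds, function(c, j) {
      mid[as.integer(j) + 1] * c
    }))
    sum(marg * 0:5) / 5 / sum(marg)
  })
  me_f2 <- local({
    conds <- tr$glutathione$conditionals$F2
    mid <- tr$glutathione$mid
    marg <- Reduce(`+`, purrr::imap(conds, function(c, j) {
      mid[as.integer(j) + 1] * c
    }))
    sum(marg * 0:5) / 5 / sum(marg)
  })
  expect_equal((5 * me_f1 + 5 * me_f2) / 10, tr$glutathione$me,
               tolerance = 1e-12)
})

test_that("GSSG labeling is the self-convolution of GSH", {
  tr <- generate_ground_truth(noise_free_params())
  gssg <- tr$gssg$mid
  expect_length(gssg, 21)
  expect_equal(sum(gssg), 1, tolerance = 1e-12)
  conv <- stats::convolve(tr$glutathione$mid, rev(tr$glutathione$mid),
                          type = "open")
  expect_equal(gssg, conv, tolerance = 1e-9)
  expect_equal(tr$gssg$me, tr$glutathione$me, tolerance = 1e-12)
})

test_that("15N truths confine label to the glutamate moiety of GSH", {
  tr <- generate_ground_truth(noise_free_params(tracer_element = "N"),
                              gsh_pathway_library("N"))
  expect_equal(tr$glycine$mid, c(1, 0))
  # F2 (cysteine + glycine nitrogens) carries no labeled mass at any shift
  for (cond in tr$glutathione$conditionals$F2) {
    expect_equal(cond[-1], rep(0, length(cond) - 1))
  }
  expect_equal(tr$glutathione$me, 0.67 * 0.23 / 3, tolerance = 1e-12)
})

test_that("noise-free, correction-free areas are proportional to the true MID", {
  lib <- gsh_pathway_library("C")
  params <- noise_free_params(purity = 1)
  params$abundance[] <- 1e6
  tr <- generate_ground_truth(params, lib)
  # remove natural abundance too: forward matrix is then the identity
  tab <- local({
    p <- params
    tab <- simulate_measurement(tr, p, "s", "g", lib, protein_ug = p$protein_mean)
    tab
  })
  # with purity 1 but natural abundance present, M0-only species still spread;
  # compare against the forward-convolved truth instead
  tracer <- tracer_spec("C", purity = 1)
  Fm <- as.matrix(correction_matrix(5, tracer))
  glu <- dplyr::filter(tab, metabolite == "glutamate", is.na(fragment))
  expect_equal(glu$area[order(glu$iso_index)] / sum(glu$area),
               as.numeric(Fm %*% tr$glutamate$mid), tolerance = 1e-10)
})

test_that("studies are deterministic given the seed", {
  s1 <- generate_study(seed = 99)
  s2 <- generate_study(seed = 99)
  expect_identical(s1$areas, s2$areas)
  s3 <- generate_study(seed = 100)
  expect_false(identical(s1$areas, s3$areas))
})

test_that("study design includes replicates and unlabeled controls per group", {
  st <- generate_study(seed = 5)
  counts <- dplyr::count(dplyr::distinct(st$areas, sample, group, control),
                         group, control)
  expect_setequal(counts$n[!counts$control], c(5, 5))
  expect_setequal(counts$n[counts$control], c(1, 1))
  # control truth is fully unlabeled
  expect_equal(st$control_truth$healthy$glutamate$mid, c(1, rep(0, 5)))
})

test_that("parameter validation rejects out-of-range settings", {
  expect_error(simulation_params(phi = 1.2), "phi")
  expect_error(simulation_params(glu_m2 = 0.8, glu_m5 = 0.5), "at most 1")
  expect_error(simulation_params(bogus = 1), "bogus")
  expect_error(simulation_params(replicates = 0), "replicates")
})
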