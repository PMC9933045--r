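test_that("protein normalization divides areas and excludes bad samples", {
  df <- tibble::tibble(sample = c("a", "b", "c"),
                       area = c(1000, 500, 100),
                       protein_ug = c(38, NA, 0))
  expect_warning(out <- normalize_by_protein(df), "Excluding 2")
  expect_equal(out$norm_area, 1000 / 38, tolerance = 1e-12)
  expect_identical(out$sample, "a")
  expect_equal(normalize_by_protein(df[1, ])$norm_area, 26.32, tolerance = 1e-3)
})

test_that("channel pools split and conserve the total area", {
  expect_equal(channel_pools(c(1, 0, 0), 50), c(unlabeled = 50, labeled = 0))
  expect_equal(channel_pools(c(0.79, 0.1, 0.11), 100),
               c(unlabeled = 79, labeled = 21))
  withr::local_seed(3)
  for (rep in 1:10) {
    m0 <- stats::runif(1)
    area <- stats::rexp(1, 1e-4)
    expect_equal(sum(channel_pools(m0, area)), area, tolerance = 1e-12)
  }
})

test_that("combined labeled fraction is area-weighted across GSH and GSSG", {
  pools <- tibble::tibble(
    sample = "s", group = "g", control = FALSE,
    metabolite = c("glutathione", "gssg"),
    total = c(100, 50),
    labeled_pool = c(30, 0),
    unlabeled_pool = c(70, 50)
  )
  out <- combined_labeled_fraction(pools)
  expect_equal(out$labeled_fraction, 0.2)
  expect_equal(out$unlabeled_fraction, 0.8)
  expect_warning(combined_labeled_fraction(pools[1, ]), "alone")
})

test_that("Welch comparison flags separations and not identical groups", {
  same <- compare_groups(c(1, 1, 1), c(1, 1, 1))
  expect_equal(same$p_value, 1)
  expect_false(same$significant)
  sep <- compare_groups(c(0, 0.01, -0.01), c(1, 1.01, 0.99))
  expect_true(sep$significant)
  few <- compare_groups(1, c(1, 2, 3))
  expect_true(is.na(few$significant))
})

test_that("null simulations flag at about the nominal alpha rate", {
  withr::local_seed(17)
  flags <- vapply(1:1000, function(i) {
    compare_groups(stats::rnorm(5), stats::rnorm(5))$significant
  }, logical(1))
  rate <- mean(flags)
  ci_half <- 1.96 * sqrt(0.05 * 0.95 / 1000)
  expect_gt(rate, 0.05 - ci_half)
  expect_lt(rate, 0.05 + ci_half)
})

test_that("pool ratios avoid infinities and track the oxidation contrast", {
  st <- generate_study(seed = 21)
  res <- suppressWarnings(run_pipeline(st))
  ratios <- dplyr::filter(res$ratios, !control)
  expect_true(all(is.finite(ratios$ratio) | is.na(ratios$ratio)))
  med <- ratios |>
    dplyr::group_by(group, channel) |>
    dplyr::summarise(m = stats::median(ratio), .groups = "drop")
  healthy <- med$m[med$group == "healthy"]
  rotenone <- med$m[med$group == "rotenone"]
  expect_true(all(rotenone < healthy))   # oxidation up, ratio down
  expect_true(all(rotenone < 10))        # stressed ratios drop below 10
  # zero denominator yields NA
  pools0 <- tibble::tibble(
    sample = "s", group = "g", control = FALSE,
    metabolite = c("glutathione", "gssg"),
    unlabeled_pool = c(10, 0), labeled_pool = c(5, 0), total = c(15, 0))
  expect_true(all(is.na(gsh_gssg_ratio(pools0)$ratio)))
})

test_that("ratios and fractions are invariant to equal protein content", {
  lib <- gsh_pathway_library("C")
  params <- noise_free_params()
  truth <- generate_ground_truth(params, lib)
  tabs <- purrr::map(c(20, 40), function(prot) {
    simulate_measurement(truth, params, paste0("s", prot), "g", lib,
                         protein_ug = prot)
  })
  tab <- dplyr::bind_rows(tabs)
  corr <- correct_study(tab, lib, tracer_spec("C", purity = 0.99))
  pools <- pool_table(enrich_study(corr, lib))
  ratios <- gsh_gssg_ratio(pools)
  by_sample <- split(ratios$ratio, ratios$sample)
  expect_equal(by_sample[[1]], by_sample[[2]], tolerance = 1e-9)
})

test_that("enrichment summary flags tracer-independent pools", {
  st <- generate_study(seed = 8)
  res <- suppressWarnings(run_pipeline(st))
  sums <- dplyr::filter(res$summary, source == "intact")
  cys <- dplyr::filter(sums, metabolite == "cysteine")
  expect_true(all(cys$no_incorporation))
  glu <- dplyr::filter(sums, metabolite == "glutamate")
  expect_true(all(!glu$no_incorporation))
  # healthy glutamate mean enrichment near the 0.60 design point
  expect_equal(glu$me_mean[glu$group == "healthy"], 0.60, tolerance = 0.05)
})

test_that("15N study flags glycine as no-incorporation", {
  st <- generate_study(simulation_params("healthy", "N"),
                       simulation_params("rotenone", "N"), seed = 4)
  res <- suppressWarnings(run_pipeline(st))
  sums <- dplyr::filter(res$summary, source == "intact")
  expect_true(all(sums$no_incorporation[sums$metabolite %in%
                                          c("glycine", "cysteine")]))
  gsh <- dplyr::filter(sums, metabolite == "glutathione", group == "healthy")
  expect_lt(abs(gsh$me_mean - 0.67 * 0.23 / 3), 0.01)
})

test_that("group comparisons support BH adjustment", {
  st <- generate_study(seed = 13)
  res <- suppressWarnings(run_pipeline(st))
  enr <- res$enriched
  raw <- group_comparisons(enr, "me", by = c("metabolite", "source"))
  adj <- group_comparisons(enr, "me", by = c("metabolite", "source"),
                           adjust = "BH")
  expect_true(all(adj$p_adjusted >= raw$p_value - 1e-15))
  expect_error(group_comparisons(dplyr::mutate(enr, group = "one"), "me",
                                 by = "metabolite"), "2 levels")
})
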