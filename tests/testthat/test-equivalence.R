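test_that("an equivalence trial yields nine well-formed p-values", {
  tr <- run_equivalence_trial(n = 2000, maf = 0.45, zero_prob = 0.66,
                              n_perm = 200, seed = 1)
  expect_s3_class(tr, "equivalence_trial")
  expect_length(tr$p_values, 9)
  expect_equal(tr$n_applicable, 9)
  expect_true(all(tr$p_values > 0 & tr$p_values <= 1))
  expect_error(run_equivalence_trial(n = 1000, n_perm = 50), "at least 100")
})

test_that("empty genotype cells are marked non-applicable, not tested", {
  # extreme MAF at small n leaves the rare homozygote cells empty
  tr <- run_equivalence_trial(n = 120, maf = 0.03, zero_prob = 0.5,
                              n_perm = 150, seed = 2)
  expect_lt(tr$n_applicable, 9)
  expect_true(any(is.na(tr$p_values)))
  expect_true(all(tr$p_values[!is.na(tr$p_values)] > 0))
})

test_that("the transform compared against itself gives null p-values", {
  tab <- generate_tuple_count_table(2000, seed = 3)
  a <- sample_ensemble(tab, 400, seed = 4)
  b <- sample_ensemble(tab, 400, seed = 5)
  pv <- countperm:::cellwise_es_pvalues(a$layer0, b$layer0)
  expect_true(all(is.na(pv) | pv > 0.001))
})

test_that("a small suite passes uniformity while the wrong sampler fails", {
  suite <- run_equivalence_suite(n_trials = 12, n = 2000, n_perm = 200,
                                 seed = 6)
  expect_s3_class(suite, "equivalence_suite")
  expect_equal(nrow(suite), 12 * 9)
  expect_true(all(suite$maf > 0.01 & suite$maf < 0.99))
  ok <- uniformity_check(suite)
  expect_gt(ok$ks_p_value, 0.001)

  neg <- run_equivalence_suite(n_trials = 12, n = 2000, n_perm = 200,
                               method = "binomial", seed = 7)
  expect_lt(uniformity_check(neg)$ks_p_value, 0.01)
})

test_that("overlay distributions agree between methods", {
  ov <- overlay_distributions(example_count_table(), n_perm = 2000, seed = 8)
  expect_s3_class(ov, "distribution_overlay")
  expect_length(ov$es_p_values, 10)
  expect_true(all(ov$es_p_values > 0.001, na.rm = TRUE))
  # per-cell means within 3 pooled standard errors
  for (cell in 1:9) {
    a <- ov$layer0_transform[, cell]
    b <- ov$layer0_naive[, cell]
    se <- sqrt(stats::var(a) / length(a) + stats::var(b) / length(b))
    if (se > 0) expect_lt(abs(mean(a) - mean(b)), 3 * se + 1e-9)
  }
  expect_error(overlay_distributions(example_count_table(), n_perm = 10),
               "at least 1000")
})

test_that("a deterministic phenotype collapses both overlays to point masses", {
  tab <- build_count_table(c(0, 1, 2, 1), c(0, 2, 1, 1), c(0, 0, 0, 0))
  ov <- overlay_distributions(tab, n_perm = 1000, seed = 9)
  expect_true(all(apply(ov$layer0_transform, 2, stats::sd) == 0))
  expect_true(all(apply(ov$layer0_naive, 2, stats::sd) == 0))
  expect_true(all(is.na(ov$es_p_values)))
})

test_that("overlay exports render to TSV and plot files", {
  ov <- overlay_distributions(example_count_table(), n_perm = 1000, seed = 10)
  tsv <- tempfile(fileext = ".tsv")
  write_overlay_tsv(ov, tsv)
  d <- read.table(tsv, header = TRUE, sep = "\t")
  expect_setequal(unique(d$method), c("transform", "naive"))
  expect_equal(sum(d$count[d$panel == "c000" & d$method == "naive"]), 1000)

  png_f <- tempfile(fileext = ".png")
  plot_overlay(ov, png_f)
  expect_gt(file.size(png_f), 1000)
  qq_f <- tempfile(fileext = ".svg")
  plot_pvalue_qq(stats::runif(200), qq_f)
  expect_gt(file.size(qq_f), 500)
})
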