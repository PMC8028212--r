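test_that("hypergeometric sampler honors its urn parameterization", {
  expect_true(all(sample_hypergeometric(10, 10, 4, nn = 50) == 4))
  expect_true(all(sample_hypergeometric(10, 0, 4, nn = 50) == 0))
  expect_true(all(sample_hypergeometric(6, 3, 0, nn = 50) == 0))
  # draws = population is a forced draw, not an error
  expect_equal(sample_hypergeometric(5, 2, 5), 2)

  # exact PMF for drawing 2 from 6 with 3 successes: {3, 9, 3} / 15
  set.seed(17)
  x <- sample_hypergeometric(6, 3, 2, nn = 100000)
  obs <- tabulate(x + 1L, 3L)
  expect_gt(stats::chisq.test(obs, p = c(3, 9, 3) / 15)$p.value, 0.001)
})

test_that("invalid hypergeometric parameters error rather than clamp", {
  expect_error(sample_hypergeometric(5, 6, 2), "successes <= population")
  expect_error(sample_hypergeometric(5, 2, 6), "draws <= population")
  expect_error(sample_hypergeometric(-1, 0, 0), "population")
  expect_error(sample_hypergeometric(5, -1, 2), "successes")
})

test_that("cell orders must enumerate the nine genotype pairs", {
  expect_s3_class(default_cell_order(), "cell_order")
  expect_setequal(as.integer(default_cell_order()), 1:9)
  # default order visits (0,0), (1,0), (2,0), (0,1), ...
  expect_identical(attr(default_cell_order(), "pairs")[1:4, 1], c(0L, 1L, 2L, 0L))
  expect_error(cell_order(matrix(0, 9, 2)), "exactly once")
  expect_error(cell_order(matrix(0:5, 3, 2)), "9x2")
})

test_that("degenerate phenotypes make the transform deterministic", {
  # all labels 0: layer 0 must equal the genotype margins, layer 1 zero
  tab <- build_count_table(c(0, 1, 2, 1), c(0, 1, 2, 2), c(0, 0, 0, 0))
  out <- transform_count_table(tab, seed = 1)
  expect_identical(unclass(out), unclass(tab))
  ens <- sample_ensemble(tab, 50, seed = 2)
  expect_true(all(ens$layer0 == matrix(as.vector(compute_margins(tab)$n_ij),
                                       50, 9, byrow = TRUE)))

  # single populated genotype cell: c*_000 is forced to n_0
  x <- array(0L, c(3, 3, 2)); x[1, 1, 1] <- 6L; x[1, 1, 2] <- 4L
  forced <- sample_ensemble(count_table(x), 100, seed = 3)
  expect_true(all(forced$layer0[, 1] == 6L))
})

test_that("transform and naive permutation share the exact joint PMF", {
  tab <- tiny_table() # n = 6, n_0 = 4
  pmf <- oracle_joint_pmf(tab)
  n_draw <- 20000
  trans <- sample_ensemble(tab, n_draw, seed = 41)
  expect_gt(pmf_chisq_pvalue(trans$layer0, pmf), 0.001)
  naive <- naive_ensemble(table = tab, n_perm = n_draw, seed = 42)
  expect_gt(pmf_chisq_pvalue(naive$layer0, pmf), 0.001)
})

test_that("conservation laws hold exactly on every sampled table", {
  set.seed(53)
  for (rep in 1:10) {
    tab <- random_table(n = sample(50:2000, 1))
    m <- compute_margins(tab)
    ens <- sample_ensemble(tab, 400)
    expect_true(all(rowSums(ens$layer0) == m$n_0))
    nij <- matrix(as.vector(m$n_ij), 400, 9, byrow = TRUE)
    expect_true(all(ens$layer0 >= 0 & ens$layer0 <= nij))
    one <- compute_margins(ensemble_table(ens, sample(400, 1)))
    expect_identical(one, m)
  }
})

test_that("every cell follows its marginal hypergeometric law", {
  tab <- generate_tuple_count_table(2000, seed = 61)
  m <- compute_margins(tab)
  N <- 20000
  ens <- sample_ensemble(tab, N, seed = 62)
  for (cell in 1:9) {
    nij <- as.vector(m$n_ij)[cell]
    mu <- nij * m$n_0 / m$n
    v <- nij * (m$n_0 / m$n) * (1 - m$n_0 / m$n) * (m$n - nij) / (m$n - 1)
    x <- ens$layer0[, cell]
    expect_lt(abs(mean(x) - mu), 3 * sqrt(v / N))
    # MC standard error of the sample variance via the fourth moment
    m4 <- mean((x - mean(x))^4)
    se_var <- sqrt(max(m4 - v^2 * (N - 3) / (N - 1), 0) / N)
    expect_lt(abs(stats::var(x) - v), 3 * se_var + 1e-9)
  }
})

test_that("the cell assignment order does not change the distribution", {
  tab <- generate_tuple_count_table(2000, seed = 71)
  row_major <- cell_order(cbind(rep(0:2, each = 3), rep(0:2, times = 3)))
  a <- sample_ensemble(tab, 4000, order = default_cell_order(), seed = 72)
  b <- sample_ensemble(tab, 4000, order = row_major, seed = 73)
  pv <- countperm:::cellwise_es_pvalues(a$layer0, b$layer0)
  expect_true(all(is.na(pv) | pv > 0.001))
  expect_gt(sum(!is.na(pv)), 6)
})

test_that("naive permutation preserves margins and fixed points", {
  s1 <- c(0, 1, 2, 0, 1); s2 <- c(2, 1, 0, 0, 2); ph <- c(0, 0, 0, 0, 0)
  expect_identical(unclass(naive_permute(s1, s2, ph, seed = 1)),
                   unclass(build_count_table(s1, s2, ph)))
  ph2 <- c(0, 1, 1, 0, 1)
  ref <- compute_margins(build_count_table(s1, s2, ph2))
  for (r in 1:5) {
    expect_identical(compute_margins(naive_permute(s1, s2, ph2, seed = r)),
                     ref)
  }
})

test_that("independent-cell sampling breaks the phenotype-0 conservation law", {
  tab <- generate_tuple_count_table(2000, seed = 81)
  m <- compute_margins(tab)
  bad <- binomial_ensemble(tab, 2000, seed = 82)
  # the negative control's layer sums fluctuate around n_0 ...
  expect_gt(stats::sd(rowSums(bad$layer0)), 0)
  # ... whereas the transform conserves them exactly
  good <- sample_ensemble(tab, 2000, seed = 83)
  expect_true(all(rowSums(good$layer0) == m$n_0))
})

test_that("per-table sampling cost is bounded by 9 draws and free of n", {
  small <- generate_tuple_count_table(100, seed = 91)
  big_counts <- unclass(small) * 10000L # n = 10^6 with the same shape
  big <- count_table(big_counts)
  e1 <- sample_ensemble(small, 10, seed = 92)
  e2 <- sample_ensemble(big, 10, seed = 93)
  expect_lte(e1$n_draws, 9L)
  expect_identical(e1$n_draws, e2$n_draws)
  expect_identical(e2$n_draws, sum(compute_margins(big)$n_ij > 0))
})

test_that("ensembles are reproducible and members materialize correctly", {
  tab <- generate_tuple_count_table(500, seed = 7)
  a <- sample_ensemble(tab, 25, seed = 99)
  b <- sample_ensemble(tab, 25, seed = 99)
  expect_identical(a$layer0, b$layer0)
  t5 <- ensemble_table(a, 5)
  expect_s3_class(t5, "count_table")
  expect_equal(as.vector(unclass(t5)[, , 1]), a$layer0[5, ])
  expect_error(ensemble_table(a, 26), "exceeds")
  expect_error(sample_ensemble(tab, 0), "integer >= 1")
})
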