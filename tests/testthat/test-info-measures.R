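# Independent direct-definition oracle: entropies computed with explicit
# loops over the probability array, sharing no code with the package's
# entropy_profile().
oracle_profile <- function(tab) {
  p <- unclass(tab) / sum(tab)
  ent <- function(v) {
    s <- 0
    for (x in v) if (x > 0) s <- s - x * log(x) / log(2)
    s
  }
  marg <- function(dims) {
    out <- apply(p, dims, sum)
    as.vector(out)
  }
  list(h1 = ent(marg(1)), h2 = ent(marg(2)), h3 = ent(marg(3)),
       h12 = ent(marg(c(1, 2))), h13 = ent(marg(c(1, 3))),
       h23 = ent(marg(c(2, 3))), h123 = ent(as.vector(p)))
}

parity_table <- function() {
  # phenotype = XOR of two binary-restricted SNPs, 4 individuals per cell
  build_count_table(rep(c(0, 1, 0, 1), each = 4),
                    rep(c(0, 1, 1, 0), each = 4),
                    rep(c(0, 0, 1, 1), each = 4))
}

test_that("probability tables are plug-in estimates", {
  x <- array(0L, c(3, 3, 2)); x[1, 1, 1] <- 2L; x[1, 1, 2] <- 2L
  p <- to_probabilities(count_table(x))
  expect_equal(p[1, 1, 1], 0.5)
  expect_equal(p[1, 1, 2], 0.5)
  expect_equal(sum(p), 1)

  ex <- to_probabilities(example_count_table())
  expect_equal(ex[2, 2, 1], 0.1576) # 1576 / 10000
  expect_equal(sum(ex), 1)
  expect_error(to_probabilities(count_table(rep(0, 18))), "empty")
})

test_that("entropy profiles match closed forms and the direct oracle", {
  # point mass: everything deterministic
  x <- array(0L, c(3, 3, 2)); x[2, 3, 1] <- 9L
  h <- entropy_profile(count_table(x))
  expect_equal(unlist(unclass(h)), setNames(rep(0, 7), names(unclass(h))))

  # parity construction: singles uniform on {0,1}, pairs uniform on 4 cells
  hp <- entropy_profile(parity_table())
  expect_equal(hp$h1, 1); expect_equal(hp$h2, 1); expect_equal(hp$h3, 1)
  expect_equal(hp$h123, 2)

  ex <- entropy_profile(example_count_table())
  expect_equal(ex$h3, -(0.6551 * log2(0.6551) + 0.3449 * log2(0.3449)))
  orc <- oracle_profile(example_count_table())
  for (nm in names(orc)) expect_equal(ex[[nm]], orc[[nm]], tolerance = 1e-9)
})

test_that("multi-information obeys its closed forms", {
  # jointly independent: all 18 cells equal
  flat <- count_table(array(5L, c(3, 3, 2)))
  expect_equal(multi_information(flat)$value, 0, tolerance = 1e-9)

  # exactly factorized product of marginals
  f1 <- c(1, 2, 1); f2 <- c(2, 1, 1); f3 <- c(3, 1)
  prod_tab <- count_table(outer(outer(f1, f2), f3))
  expect_equal(multi_information(prod_tab)$value, 0, tolerance = 1e-9)

  # pure three-way interaction: 1 + 1 + 1 - 2 = 1 bit
  expect_equal(multi_information(parity_table())$value, 1)

  # reference table against the direct-definition oracle
  orc <- oracle_profile(example_count_table())
  omega_oracle <- orc$h1 + orc$h2 + orc$h3 - orc$h123
  expect_equal(multi_information(example_count_table())$value, omega_oracle,
               tolerance = 1e-9)
  expect_gte(omega_oracle, 0)
})

test_that("multi-information is invariant under category relabeling", {
  tab <- generate_tuple_count_table(1000, seed = 3)
  a <- unclass(tab)
  ref <- multi_information(tab)$value
  perm <- sample(3)
  expect_equal(multi_information(count_table(a[perm, , ]))$value, ref)
  expect_equal(multi_information(count_table(a[, perm, ]))$value, ref)
  expect_equal(multi_information(count_table(a[, , 2:1]))$value, ref)
})

test_that("the measure registry resolves names and custom measures", {
  tab <- example_count_table()
  expect_true("multi_information" %in% list_measures())
  expect_equal(apply_measure(tab, "multi_information")$value,
               multi_information(tab)$value)
  expect_error(apply_measure(tab, "no_such_measure"), "unknown measure")

  register_measure("mi_snp_snp", function(h) h$h1 + h$h2 - h$h12)
  got <- apply_measure(tab, "mi_snp_snp")$value
  orc <- oracle_profile(tab)
  expect_equal(got, orc$h1 + orc$h2 - orc$h12, tolerance = 1e-9)

  # any difference-of-entropies measure vanishes on a deterministic table
  x <- array(0L, c(3, 3, 2)); x[1, 1, 1] <- 4L
  expect_equal(apply_measure(count_table(x), "mi_snp_snp")$value, 0)
})

test_that("vectorized ensemble measures agree with per-table evaluation", {
  tab <- generate_tuple_count_table(800, seed = 5)
  ens <- sample_ensemble(tab, 30, seed = 6)
  vec <- ensemble_measure(ens, "multi_information")
  per <- vapply(1:30, function(i) {
    multi_information(ensemble_table(ens, i))$value
  }, numeric(1))
  expect_equal(vec, per, tolerance = 1e-9)
})

test_that("plug-in bias of the null mean decreases with cohort size", {
  means <- vapply(c(100, 1000, 10000), function(n) {
    tab <- generate_tuple_count_table(n, seed = 900 + n)
    mean(ensemble_measure(sample_ensemble(tab, 2000, seed = n),
                          "multi_information"))
  }, numeric(1))
  expect_true(all(diff(means) < 0))
  expect_true(all(means > 0))
})
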