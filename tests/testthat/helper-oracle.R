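# Exact label-permutation oracle for small cohorts: enumerate every
# distinct placement of the n_0 phenotype-0 labels over the n individuals
# and tally the resulting phenotype-0 layers. Returns the exact joint PMF
# of the layer-0 vector as a named numeric vector, keys "c1,...,c9".
oracle_joint_pmf <- function(tab) {
  a <- unclass(tab)
  nij <- as.vector(a[, , 1] + a[, , 2])
  n0 <- sum(a[, , 1])
  n <- sum(nij)
  stopifnot(n <= 10) # enumeration only
  cells <- rep.int(1:9, nij)
  subsets <- utils::combn(n, n0)
  keys <- apply(subsets, 2, function(s) {
    paste(tabulate(cells[s], nbins = 9), collapse = ",")
  })
  tt <- table(keys)
  pmf <- as.numeric(tt) / ncol(subsets)
  names(pmf) <- names(tt)
  pmf
}

layer0_keys <- function(layer0) {
  apply(layer0, 1, paste, collapse = ",")
}

# chi-square goodness of fit of sampled layer-0 vectors against an exact
# PMF over a finite support; returns the test p-value.
pmf_chisq_pvalue <- function(layer0, pmf) {
  keys <- layer0_keys(layer0)
  stopifnot(all(keys %in% names(pmf))) # support must match exactly
  obs <- table(factor(keys, levels = names(pmf)))
  suppressWarnings(stats::chisq.test(as.numeric(obs), p = pmf)$p.value)
}

# small deterministic count table used across tests:
# two individuals (0,0,phen 0), one (0,0,1), two (1,1,0), one (1,1,1)
tiny_table <- function() {
  build_count_table(c(0, 0, 0, 1, 1, 1), c(0, 0, 0, 1, 1, 1),
                    c(0, 1, 0, 0, 1, 0))
}

# random valid count table with margins drawn from a Dirichlet-free
# recipe: multinomial cells over random probabilities, random n_0 split
random_table <- function(n = 500) {
  probs <- as.vector(stats::rmultinom(1, 100, rep(1 / 18, 18)) + 1)
  count_table(array(as.vector(stats::rmultinom(1, n, probs)), c(3, 3, 2)))
}
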