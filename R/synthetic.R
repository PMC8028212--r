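#' Simulate one SNP column under Hardy-Weinberg equilibrium
#'
#' Draws `n` independent genotypes with minor allele frequency `maf`,
#' assuming perfect Hardy-Weinberg equilibrium: the genotype value is 0
#' with probability `maf^2`, 1 with probability `2 * maf * (1 - maf)`, and
#' 2 with probability `(1 - maf)^2`. Defaults reproduce the package's
#' reference null scenario (maf = 0.45).
#'
#' @param n number of individuals.
#' @param maf minor allele frequency, strictly in (0, 1).
#' @param seed optional integer seed; the caller's RNG state is restored
#'   afterwards. With `seed = NULL` the current RNG stream is consumed.
#' @return integer vector of length `n` with values in \{0, 1, 2\}.
#' @examples
#' table(generate_snp(1000, maf = 0.45, seed = 1))
#' @export
generate_snp <- function(n, maf = 0.45, seed = NULL) {
  n <- check_count(n, "n")
  maf <- check_fraction(maf, "maf")
  probs <- c(maf^2, 2 * maf * (1 - maf), (1 - maf)^2)
  with_seed(seed, {
    sample.int(3L, n, replace = TRUE, prob = probs) - 1L
  })
}

#' Simulate a binary phenotype vector
#'
#' Draws `n` independent case/control labels with `P(0) = zero_prob`.
#' Defaults reproduce the package's reference null scenario
#' (`zero_prob = 0.66`).
#'
#' @param n number of individuals.
#' @param zero_prob probability of the 0 (control) label, strictly in
#'   (0, 1).
#' @inheritParams generate_snp
#' @return integer vector of length `n` with values in \{0, 1\}.
#' @examples
#' mean(generate_phenotype(1000, zero_prob = 0.66, seed = 1) == 0)
#' @export
generate_phenotype <- function(n, zero_prob = 0.66, seed = NULL) {
  n <- check_count(n, "n")
  zero_prob <- check_fraction(zero_prob, "zero_prob")
  with_seed(seed, {
    as.integer(runif(n) >= zero_prob)
  })
}

#' Simulate a full genotype matrix of independent SNPs
#'
#' Convenience wrapper generating `m` independent Hardy-Weinberg SNP
#' columns (no linkage disequilibrium, no phenotype effect: a pure null
#' generator).
#'
#' @param n number of individuals (rows).
#' @param m number of SNPs (columns).
#' @inheritParams generate_snp
#' @return an `n` x `m` integer matrix with column names `snp1..snpm` and
#'   row names `ind1..indn`.
#' @export
generate_genotype_matrix <- function(n, m, maf = 0.45, seed = NULL) {
  n <- check_count(n, "n")
  m <- check_count(m, "m")
  maf <- check_fraction(maf, "maf")
  with_seed(seed, {
    g <- matrix(sample.int(3L, n * m, replace = TRUE,
                           prob = c(maf^2, 2 * maf * (1 - maf), (1 - maf)^2)) - 1L,
                nrow = n, ncol = m)
    dimnames(g) <- list(paste0("ind", seq_len(n)), paste0("snp", seq_len(m)))
    g
  })
}

#' Simulate a null two-SNP-phenotype count table
#'
#' Generates two independent Hardy-Weinberg SNP columns and an independent
#' binary phenotype, and tallies them into a count table. Because the three
#' variables are mutually independent, the result is a draw from the global
#' null of no SNP-SNP-phenotype association.
#'
#' @inheritParams generate_snp
#' @inheritParams generate_phenotype
#' @return a [count_table()] whose entries sum to `n`.
#' @examples
#' tab <- generate_tuple_count_table(10000, seed = 1)
#' compute_margins(tab)$n
#' @export
generate_tuple_count_table <- function(n, maf = 0.45, zero_prob = 0.66,
                                       seed = NULL) {
  n <- check_count(n, "n")
  maf <- check_fraction(maf, "maf")
  zero_prob <- check_fraction(zero_prob, "zero_prob")
  with_seed(seed, {
    build_count_table(generate_snp(n, maf),
                      generate_snp(n, maf),
                      generate_phenotype(n, zero_prob))
  })
}

#' Reference null count table shipped with the package
#'
#' Loads the stored realization of the Hardy-Weinberg null generator
#' (n = 10,000 individuals, minor allele frequency 0.45, phenotype-0
#' probability 0.66) used throughout the documentation and validation
#' examples.
#'
#' @return a [count_table()] with 10,000 individuals.
#' @examples
#' compute_margins(example_count_table())
#' @export
example_count_table <- function() {
  read_count_table(system.file("extdata", "hw_null_counts.json",
                               package = "countperm", mustWork = TRUE))
}
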