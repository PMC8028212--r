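#' Hypergeometric sampler with an explicit urn parameterization
#'
#' Draws the number of successes obtained when `draws` items are taken
#' without replacement from a population of `population` items of which
#' `successes` are successes. This thin wrapper around [stats::rhyper()]
#' pins the parameterization used throughout the package so that
#' library-convention differences (white/black balls vs
#' population/successes) cannot leak into the count-table transform, and
#' it rejects invalid parameters rather than clamping them.
#'
#' @param population total number of items in the urn.
#' @param successes number of success items, `0 <= successes <=
#'   population`.
#' @param draws number of items drawn, `0 <= draws <= population`.
#' @param nn number of independent replicates to draw (each of
#'   `population`, `successes`, `draws` may be a vector recycled to `nn`).
#' @return integer vector of length `nn`, each value in
#'   `[max(0, draws - (population - successes)), min(draws, successes)]`.
#' @examples
#' sample_hypergeometric(10, 10, 4)  # always 4
#' table(sample_hypergeometric(6, 3, 2, nn = 1000))
#' @export
sample_hypergeometric <- function(population, successes, draws, nn = 1L) {
  if (any(!is.finite(population)) || any(!is.finite(successes)) ||
      any(!is.finite(draws))) {
    stop("hypergeometric parameters must be finite", call. = FALSE)
  }
  if (any(population < 0) || any(successes < 0) || any(draws < 0) ||
      any(successes > population) || any(draws > population)) {
    stop("require 0 <= successes <= population and 0 <= draws <= population",
         call. = FALSE)
  }
  rhyper(nn, m = successes, n = population - successes, k = draws)
}

#' Cell assignment order for the count-table transform
#'
#' The transform fills the nine genotype cells one at a time; `cell_order`
#' fixes the order in which they are visited. The default visits (SNP1,
#' SNP2) index pairs as (0,0), (1,0), (2,0), (0,1), ..., (2,2) — i.e.
#' column-major over the 3x3 genotype grid. The choice is cosmetic: any
#' order yields the same sampling distribution (exchangeability of the
#' label draw), which the test suite verifies.
#'
#' @param pairs a 9x2 integer matrix of (i, j) genotype index pairs, each
#'   of the nine pairs exactly once, 0-based.
#' @return an object of class `cell_order`: an integer permutation of 1:9
#'   in linear (column-major) cell indexing, carrying the `pairs` matrix
#'   as an attribute.
#' @examples
#' default_cell_order()
#' cell_order(cbind(rep(0:2, each = 3), rep(0:2, times = 3)))  # row-major
#' @export
cell_order <- function(pairs) {
  pairs <- as.matrix(pairs)
  if (!is.numeric(pairs) || any(dim(pairs) != c(9L, 2L)) ||
      any(!(pairs %in% 0:2))) {
    stop("`pairs` must be a 9x2 matrix of genotype indices in {0, 1, 2}",
         call. = FALSE)
  }
  lin <- as.integer(1L + pairs[, 1L] + 3L * pairs[, 2L])
  if (!setequal(lin, 1:9)) {
    stop("`pairs` must contain each of the nine (i, j) pairs exactly once",
         call. = FALSE)
  }
  structure(lin, pairs = pairs, class = "cell_order")
}

#' @rdname cell_order
#' @export
default_cell_order <- function() {
  cell_order(cbind(rep(0:2, times = 3), rep(0:2, each = 3)))
}

# Core sampler: N transformed phenotype-0 layers for the given margins.
# Returns an N x 9 integer matrix in linear (column-major) cell order.
# Cells are visited in `order`; each visited cell (i,j) draws
#   c*_ij0 ~ Hypergeometric(pop_remaining, zeros_remaining, n_ij)
# where the remainders subtract everything assigned at earlier cells.
# Empty genotype cells (n_ij = 0) contribute a deterministic 0 and no
# random draw, so the per-table draw count equals the number of populated
# cells (at most 9) regardless of n.
sample_layer0 <- function(margins, n_perm, order = default_cell_order()) {
  stopifnot(inherits(margins, "genotype_margins"))
  if (!inherits(order, "cell_order")) order <- cell_order(order)
  nij <- as.vector(margins$n_ij)[order]
  pop_rem <- margins$n - c(0L, cumsum(nij))[1:9]
  out <- matrix(0L, nrow = n_perm, ncol = 9L)
  zeros_rem <- rep.int(margins$n_0, n_perm)
  n_draws <- 0L
  for (s in 1:9) {
    k <- nij[s]
    if (k == 0L) next
    n_draws <- n_draws + 1L
    x <- sample_hypergeometric(pop_rem[s], zeros_rem, k, nn = n_perm)
    out[, order[s]] <- x
    zeros_rem <- zeros_rem - x
  }
  attr(out, "n_draws") <- n_draws
  out
}

#' Directly sample one permuted count table
#'
#' Produces a count table distributed exactly as if the phenotype labels
#' had been uniformly permuted and the table re-tallied, without touching
#' any individual-level data. The phenotype-0 layer is filled cell by cell
#' with hypergeometric draws from the shrinking pool of unassigned labels;
#' the phenotype-1 layer is the genotype margin minus the phenotype-0
#' layer. Margins of the output always equal margins of the input.
#'
#' @param table a [count_table()].
#' @param order a [cell_order()]; the default is fine (the order does not
#'   affect the distribution).
#' @inheritParams generate_snp
#' @return a [count_table()] with the same margins as `table`.
#' @examples
#' tab <- generate_tuple_count_table(1000, seed = 1)
#' transform_count_table(tab, seed = 2)
#' @export
transform_count_table <- function(table, order = default_cell_order(),
                                  seed = NULL) {
  table <- as_count_table(table)
  m <- compute_margins(table)
  layer0 <- with_seed(seed, sample_layer0(m, 1L, order))
  l0 <- matrix(layer0[1L, ], 3L, 3L)
  count_table(array(c(l0, m$n_ij - l0), dim = c(3L, 3L, 2L)))
}

new_ensemble <- function(layer0, margins, method, seed) {
  structure(list(layer0 = layer0, margins = margins, method = method,
                 n_perm = nrow(layer0), seed = seed,
                 n_draws = attr(layer0, "n_draws")),
            class = "permuted_ensemble")
}

#' @export
print.permuted_ensemble <- function(x, ...) {
  cat(sprintf("permuted ensemble: %d tables (method = %s, n = %d, n_0 = %d)\n",
              x$n_perm, x$method, x$margins$n, x$margins$n_0))
  invisible(x)
}

#' Sample an ensemble of permuted count tables
#'
#' Draws `n_perm` independent permuted count tables from the label
#' permutation null of `table` using the direct hypergeometric transform.
#' Only the phenotype-0 layer varies between members (the margins are
#' fixed), so the ensemble is stored compactly as an `n_perm` x 9 matrix;
#' use [ensemble_table()] to materialize any member as a full
#' [count_table()]. The sampler is vectorized across the ensemble: the
#' whole batch costs nine hypergeometric draw calls however large `n` or
#' `n_perm` is.
#'
#' @inheritParams transform_count_table
#' @param n_perm number of permuted tables.
#' @return an object of class `permuted_ensemble` with elements `layer0`
#'   (`n_perm` x 9 integer matrix of phenotype-0 counts, column-major cell
#'   order), `margins`, `method` (`"transform"`), `n_perm`, `seed`, and
#'   `n_draws` (random draws used per table — the number of populated
#'   genotype cells).
#' @examples
#' tab <- generate_tuple_count_table(1000, seed = 1)
#' ens <- sample_ensemble(tab, n_perm = 100, seed = 2)
#' colMeans(ens$layer0)
#' @export
sample_ensemble <- function(table, n_perm, order = default_cell_order(),
                            seed = NULL) {
  table <- as_count_table(table)
  n_perm <- check_count(n_perm, "n_perm")
  m <- compute_margins(table)
  layer0 <- with_seed(seed, sample_layer0(m, n_perm, order))
  new_ensemble(layer0, m, "transform", seed)
}

#' Materialize one member of a permuted ensemble
#'
#' @param ensemble a `permuted_ensemble`.
#' @param i member index in `1:n_perm`.
#' @return a [count_table()].
#' @export
ensemble_table <- function(ensemble, i) {
  stopifnot(inherits(ensemble, "permuted_ensemble"))
  i <- check_count(i, "i")
  if (i > ensemble$n_perm) stop("`i` exceeds ensemble size", call. = FALSE)
  l0 <- matrix(ensemble$layer0[i, ], 3L, 3L)
  count_table(array(c(l0, ensemble$margins$n_ij - l0), dim = c(3L, 3L, 2L)))
}

#' Naive permutation of a single tuple
#'
#' The reference method the transform must match: uniformly permute the
#' phenotype labels of the complete-case individuals and re-tally the
#' count table from the raw columns. Cost is O(n) per permutation.
#'
#' @inheritParams build_count_table
#' @inheritParams generate_snp
#' @return a [count_table()].
#' @export
naive_permute <- function(snp1, snp2, phenotype, seed = NULL) {
  if (length(snp1) != length(snp2) || length(snp1) != length(phenotype)) {
    stop("`snp1`, `snp2` and `phenotype` must have the same length",
         call. = FALSE)
  }
  snp1 <- validate_genotype_column(snp1, "snp1")
  snp2 <- validate_genotype_column(snp2, "snp2")
  phenotype <- validate_phenotype(phenotype)
  keep <- !(is.na(snp1) | is.na(snp2) | is.na(phenotype))
  with_seed(seed, {
    build_count_table(snp1[keep], snp2[keep], sample(phenotype[keep]))
  })
}

#' Ensemble of naively permuted count tables
#'
#' Repeats label shuffling and re-tallying `n_perm` times, either from raw
#' genotype/phenotype columns or from a count table alone (a count table
#' determines the individual-level multiset up to reordering, which is all
#' a label permutation can see). Used as the oracle in equivalence
#' validation; for production scans use [sample_ensemble()].
#'
#' @param table a [count_table()]; mutually exclusive with the raw
#'   columns.
#' @inheritParams build_count_table
#' @inheritParams sample_ensemble
#' @return a `permuted_ensemble` with `method = "naive"`.
#' @export
naive_ensemble <- function(table = NULL, snp1 = NULL, snp2 = NULL,
                           phenotype = NULL, n_perm, seed = NULL) {
  n_perm <- check_count(n_perm, "n_perm")
  if (is.null(table)) {
    if (is.null(snp1) || is.null(snp2) || is.null(phenotype)) {
      stop("supply either `table` or all of `snp1`, `snp2`, `phenotype`",
           call. = FALSE)
    }
    snp1 <- validate_genotype_column(snp1, "snp1")
    snp2 <- validate_genotype_column(snp2, "snp2")
    phenotype <- validate_phenotype(phenotype)
    keep <- !(is.na(snp1) | is.na(snp2) | is.na(phenotype))
    cell <- 1L + snp1[keep] + 3L * snp2[keep]
    phen <- phenotype[keep]
    margins <- compute_margins(build_count_table(snp1, snp2, phenotype))
  } else {
    ind <- expand_count_table(table)
    cell <- ind$cell
    phen <- ind$phenotype
    margins <- compute_margins(table)
  }
  n <- length(cell)
  layer0 <- matrix(0L, nrow = n_perm, ncol = 9L)
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      shuffled <- phen[sample.int(n)]
      layer0[b, ] <- tabulate(cell[shuffled == 0L], nbins = 9L)
    }
  })
  attr(layer0, "n_draws") <- NA_integer_
  new_ensemble(layer0, margins, "naive", seed)
}

#' Independent-binomial sampler (negative control)
#'
#' Deliberately wrong sampler used to demonstrate that the validation
#' suite has power: each phenotype-0 cell is drawn independently as
#' Binomial(n_ij, n_0 / n). The marginal cell means match the permutation
#' null, but the cells are sampled independently, so the phenotype-0 total
#' is no longer conserved and the joint (and per-cell) distributions are
#' wrong. Never use for inference.
#'
#' @inheritParams sample_ensemble
#' @return a `permuted_ensemble` with `method = "binomial"`.
#' @export
binomial_ensemble <- function(table, n_perm, seed = NULL) {
  table <- as_count_table(table)
  n_perm <- check_count(n_perm, "n_perm")
  m <- compute_margins(table)
  nij <- as.vector(m$n_ij)
  layer0 <- with_seed(seed, {
    matrix(rbinom(n_perm * 9L, size = rep(nij, each = n_perm),
                  prob = m$n_0 / m$n),
           nrow = n_perm, ncol = 9L)
  })
  attr(layer0, "n_draws") <- sum(nij > 0L)
  new_ensemble(layer0, m, "binomial", seed)
}
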