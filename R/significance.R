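#' Permutation null distribution of a measure for one tuple
#'
#' Samples `n_perm` permuted count tables with the direct hypergeometric
#' transform (or the naive shuffle, for cross-checking) and evaluates the
#' measure on each, giving the empirical null distribution of the measure
#' for this tuple's margins.
#'
#' @inheritParams sample_ensemble
#' @inheritParams apply_measure
#' @param method `"transform"` (default, O(1) in n per table) or
#'   `"naive"` (label shuffling on the table's expanded multiset; O(n)
#'   per table, reference only).
#' @return an object of class `null_distribution`: list with `values`
#'   (length `n_perm` numeric), `measure_name`, `n_perm`, `method`,
#'   `seed`.
#' @examples
#' nd <- null_distribution(example_count_table(), n_perm = 200, seed = 1)
#' quantile(nd$values, c(0.5, 0.95))
#' @export
null_distribution <- function(table, measure = "multi_information",
                              n_perm, method = c("transform", "naive"),
                              seed = NULL) {
  method <- match.arg(method)
  table <- as_count_table(table)
  n_perm <- check_count(n_perm, "n_perm")
  ens <- if (method == "transform") {
    sample_ensemble(table, n_perm, seed = seed)
  } else {
    naive_ensemble(table = table, n_perm = n_perm, seed = seed)
  }
  m <- resolve_measure(measure)
  structure(list(values = ensemble_measure(ens, measure),
                 measure_name = m$name, n_perm = n_perm,
                 method = method, seed = seed),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("null distribution of %s: %d permutations (%s)\n",
              x$measure_name, x$n_perm, x$method))
  print(summary(x$values))
  invisible(x)
}

#' Add-one empirical permutation p-value
#'
#' `p = (1 + #\{null >= observed\}) / (1 + n_perm)`, the standard
#' bias-safe permutation estimator: ties count toward the tail and the
#' smallest attainable value is `1 / (n_perm + 1)`, never 0. One-sided
#' upper tail, appropriate for non-negative dependence measures where
#' larger means stronger association.
#'
#' @param observed observed measure value (a `measure_value` or a single
#'   number).
#' @param null a `null_distribution` (or a numeric vector of null
#'   values).
#' @return a single number in `(0, 1]`.
#' @examples
#' empirical_pvalue(0.5, c(0.1, 0.2, 0.6))  # (1 + 1) / (1 + 3)
#' @export
empirical_pvalue <- function(observed, null) {
  obs <- if (inherits(observed, "measure_value")) observed$value else observed
  vals <- if (inherits(null, "null_distribution")) null$values else null
  if (!is.numeric(obs) || length(obs) != 1L || is.na(obs)) {
    stop("`observed` must be a single measure value", call. = FALSE)
  }
  if (length(vals) < 1L) stop("`null` must be non-empty", call. = FALSE)
  (1 + sum(vals >= obs)) / (1 + length(vals))
}

#' Pairwise SNP interaction scan with per-tuple permutation nulls
#'
#' For each requested SNP pair, tallies the count table once from the
#' genotype matrix, evaluates the observed measure, samples its
#' permutation null with the direct transform (never re-touching the
#' n x m matrix), and reports the add-one empirical p-value. Each pair
#' uses an RNG sub-seed derived from (`seed`, pair row index), so results
#' are reproducible and independent of execution order.
#'
#' @param genotypes n x m integer matrix of genotypes in \{0, 1, 2, NA\}
#'   with SNP identifiers as column names.
#' @param phenotype length-n vector in \{0, 1, NA\}.
#' @param pairs two-column matrix (or data.frame) of SNP column indices
#'   (or column names) to test; `NULL` means all `choose(m, 2)` pairs.
#' @inheritParams null_distribution
#' @param seed integer seed driving all per-pair sub-streams (required
#'   for reproducibility; defaults to 1).
#' @return a data.frame with one row per pair: `snp1`, `snp2`,
#'   `observed` (measure value, bits), `p_value`, `n_perm`, `seed`.
#' @examples
#' g <- generate_genotype_matrix(500, 4, seed = 1)
#' ph <- generate_phenotype(500, seed = 2)
#' scan_pairs(g, ph, n_perm = 99, seed = 3)
#' @export
scan_pairs <- function(genotypes, phenotype, pairs = NULL,
                       measure = "multi_information", n_perm = 999L,
                       seed = 1L) {
  genotypes <- as.matrix(genotypes)
  if (nrow(genotypes) != length(phenotype)) {
    stop("`genotypes` rows and `phenotype` length differ", call. = FALSE)
  }
  phenotype <- validate_phenotype(phenotype)
  m <- ncol(genotypes)
  ids <- colnames(genotypes) %||% paste0("snp", seq_len(m))
  if (is.null(pairs)) {
    if (m < 2L) stop("need at least two SNP columns", call. = FALSE)
    pairs <- t(utils::combn(m, 2L))
  }
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2L) stop("`pairs` must have two columns", call. = FALSE)
  if (nrow(pairs) == 0L) {
    return(data.frame(snp1 = character(), snp2 = character(),
                      observed = numeric(), p_value = numeric(),
                      n_perm = integer(), seed = integer()))
  }
  if (is.character(pairs)) {
    idx <- matrix(match(pairs, ids), ncol = 2L)
    if (anyNA(idx)) stop("unknown SNP identifiers in `pairs`", call. = FALSE)
    pairs <- idx
  }
  if (any(pairs < 1L) || any(pairs > m)) {
    stop("pair indices out of range 1..m", call. = FALSE)
  }
  measure_r <- resolve_measure(measure)
  n_perm <- check_count(n_perm, "n_perm")
  seed <- check_count(seed, "seed", min = 0)

  res <- vector("list", nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1L]; j <- pairs[r, 2L]
    tab <- build_count_table(genotypes[, i], genotypes[, j], phenotype)
    obs <- apply_measure(tab, measure_r$fn)$value
    sub <- derive_seed(seed, r)
    nd <- null_distribution(tab, measure_r$fn, n_perm = n_perm,
                            seed = sub)
    res[[r]] <- data.frame(snp1 = ids[i], snp2 = ids[j], observed = obs,
                           p_value = empirical_pvalue(obs, nd),
                           n_perm = n_perm, seed = sub)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
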