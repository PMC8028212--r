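# Entropies are reported in bits (log base 2) throughout. 0 log 0 is
# taken as 0 by masking zero cells rather than adding a pseudocount,
# which would bias the interaction measures.
xlog2x_sum <- function(p) {
  p <- p[p > 0]
  sum(p * log2(p))
}

shannon_entropy <- function(p) -xlog2x_sum(p)

#' Plug-in joint probability estimates from a count table
#'
#' Divides the count table by its total, giving the maximum-likelihood
#' (plug-in) estimate of the joint distribution of (SNP1, SNP2,
#' phenotype).
#'
#' @param table a [count_table()].
#' @return a 3x3x2 numeric array summing to 1.
#' @examples
#' to_probabilities(example_count_table())[2, 2, 1]  # = 1576 / 10000
#' @export
to_probabilities <- function(table) {
  table <- as_count_table(table)
  n <- attr(table, "total")
  if (n < 1L) stop("count table is empty (total = 0)", call. = FALSE)
  array(as.numeric(table) / n, dim = c(3L, 3L, 2L),
        dimnames = dimnames(table))
}

#' Marginal and joint Shannon entropies of a count table
#'
#' Computes the plug-in Shannon entropies (base 2, in bits) of each
#' variable, each pair of variables, and the full triple, from the joint
#' probability estimate. Every interaction measure supported by the
#' package is a function of this profile.
#'
#' @param table a [count_table()].
#' @return an object of class `entropy_profile`: a named list with
#'   entropies `h1`, `h2`, `h3` (SNP1, SNP2, phenotype), `h12`, `h13`,
#'   `h23`, and `h123`, all in bits.
#' @examples
#' entropy_profile(example_count_table())
#' @export
entropy_profile <- function(table) {
  p <- to_probabilities(table)
  structure(list(
    h1 = shannon_entropy(apply(p, 1L, sum)),
    h2 = shannon_entropy(apply(p, 2L, sum)),
    h3 = shannon_entropy(apply(p, 3L, sum)),
    h12 = shannon_entropy(apply(p, c(1L, 2L), sum)),
    h13 = shannon_entropy(apply(p, c(1L, 3L), sum)),
    h23 = shannon_entropy(apply(p, c(2L, 3L), sum)),
    h123 = shannon_entropy(as.vector(p))
  ), class = "entropy_profile")
}

#' @export
print.entropy_profile <- function(x, ...) {
  v <- unlist(unclass(x))
  cat("entropy profile (bits):\n")
  print(round(v, 6))
  invisible(x)
}

# --- measure registry ---------------------------------------------------

# A measure is a function of the entropy profile. Registered functions
# receive the profile fields as a list whose elements may be vectors (one
# value per ensemble member), so any measure written with vectorized
# arithmetic evaluates on whole null ensembles at no extra cost.
.measures <- new.env(parent = emptyenv())

#' Register a named interaction measure
#'
#' Adds a measure to the package registry. A measure is any scalar
#' function of the entropy profile; `fn` receives a list with fields
#' `h1`, `h2`, `h3`, `h12`, `h13`, `h23`, `h123` (possibly vector-valued
#' when evaluated over a null ensemble) and must return a numeric of the
#' same length using vectorized arithmetic.
#'
#' @param name measure identifier.
#' @param fn function of the entropy profile.
#' @return `name`, invisibly.
#' @examples
#' register_measure("mi_snp1_snp2", function(h) h$h1 + h$h2 - h$h12)
#' "mi_snp1_snp2" %in% list_measures()
#' @export
register_measure <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  assign(name, fn, envir = .measures)
  invisible(name)
}

#' @rdname register_measure
#' @export
list_measures <- function() sort(ls(.measures))

resolve_measure <- function(measure) {
  if (is.function(measure)) {
    return(list(name = "custom", fn = measure))
  }
  if (!is.character(measure) || length(measure) != 1L) {
    stop("`measure` must be a registered measure name or a function",
         call. = FALSE)
  }
  if (!exists(measure, envir = .measures, inherits = FALSE)) {
    stop(sprintf("unknown measure '%s'; registered measures: %s", measure,
                 paste(list_measures(), collapse = ", ")), call. = FALSE)
  }
  list(name = measure, fn = get(measure, envir = .measures))
}

# multi-information (total correlation) of the triple: sum of the single
# variable entropies minus the joint entropy; zero iff the three
# variables are jointly independent, non-negative otherwise.
register_measure("multi_information",
                 function(h) h$h1 + h$h2 + h$h3 - h$h123)

#' Evaluate a registered measure on a count table
#'
#' @param table a [count_table()].
#' @param measure a registered measure name (see [list_measures()]) or a
#'   function of the entropy profile.
#' @return an object of class `measure_value`: list with `name` and
#'   `value` (bits).
#' @examples
#' apply_measure(example_count_table(), "multi_information")
#' @export
apply_measure <- function(table, measure) {
  m <- resolve_measure(measure)
  h <- entropy_profile(table)
  structure(list(name = m$name, value = as.numeric(m$fn(unclass(h)))),
            class = "measure_value")
}

#' @export
print.measure_value <- function(x, ...) {
  cat(sprintf("%s = %.6g bits\n", x$name, x$value))
  invisible(x)
}

#' Multi-information of a two-SNP-phenotype count table
#'
#' The total correlation Omega = H1 + H2 + H3 - H123 of the two SNPs and
#' the phenotype, in bits: zero when the three variables are jointly
#' independent, and strictly positive under any joint dependence
#' (including pure SNP-SNP-phenotype interaction with independent
#' marginals). Estimated by plug-in entropies with no bias correction.
#'
#' @param table a [count_table()].
#' @return a `measure_value`.
#' @examples
#' multi_information(example_count_table())
#' @export
multi_information <- function(table) {
  apply_measure(table, "multi_information")
}

# --- vectorized evaluation over ensembles -------------------------------

# Entropy profiles for every member of a permuted ensemble, computed with
# matrix arithmetic on the N x 9 phenotype-0 layer. The genotype margins
# are permutation-invariant, so h1, h2 and h12 are constants; only the
# phenotype-involving entropies vary across members.
ensemble_entropy_profiles <- function(ensemble) {
  stopifnot(inherits(ensemble, "permuted_ensemble"))
  m <- ensemble$margins
  n <- m$n
  if (n < 1L) stop("count table is empty (total = 0)", call. = FALSE)
  L0 <- ensemble$layer0
  nij <- as.vector(m$n_ij)
  L1 <- matrix(nij, nrow = nrow(L0), ncol = 9L, byrow = TRUE) - L0

  pij <- nij / n
  h12 <- shannon_entropy(pij)
  h1 <- shannon_entropy(rowSums(m$n_ij) / n)
  h2 <- shannon_entropy(colSums(m$n_ij) / n)

  ent_rows <- function(P) {
    X <- ifelse(P > 0, P * log2(P), 0)
    -rowSums(X)
  }

  P0 <- L0 / n
  P1 <- L1 / n
  h123 <- ent_rows(cbind(P0, P1))

  p0 <- rowSums(P0) # scalar n_0/n replicated, but compute for generality
  h3 <- ent_rows(cbind(p0, 1 - p0))

  # aggregate cells over SNP2 (columns of the 3x3 grid share j) and SNP1
  agg1 <- matrix(0, 9L, 3L) # cell -> SNP1 level
  agg2 <- matrix(0, 9L, 3L) # cell -> SNP2 level
  for (cell in 1:9) {
    i <- (cell - 1L) %% 3L + 1L
    j <- (cell - 1L) %/% 3L + 1L
    agg1[cell, i] <- 1
    agg2[cell, j] <- 1
  }
  h13 <- ent_rows(cbind(P0 %*% agg1, P1 %*% agg1))
  h23 <- ent_rows(cbind(P0 %*% agg2, P1 %*% agg2))

  data.frame(h1 = h1, h2 = h2, h3 = h3, h12 = h12,
             h13 = h13, h23 = h23, h123 = h123)
}

#' Evaluate a measure on every member of a permuted ensemble
#'
#' Vectorized convenience: computes the entropy profile of each member
#' table and applies the measure, without materializing the tables.
#'
#' @param ensemble a `permuted_ensemble` (see [sample_ensemble()]).
#' @inheritParams apply_measure
#' @return numeric vector of length `ensemble$n_perm`, in bits.
#' @examples
#' ens <- sample_ensemble(example_count_table(), 50, seed = 1)
#' summary(ensemble_measure(ens, "multi_information"))
#' @export
ensemble_measure <- function(ensemble, measure = "multi_information") {
  m <- resolve_measure(measure)
  h <- ensemble_entropy_profiles(ensemble)
  as.numeric(m$fn(as.list(h)))
}
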