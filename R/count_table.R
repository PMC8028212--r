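#' Count table for a two-SNP / binary-phenotype tuple
#'
#' A count table is a 3x3x2 array of non-negative integers `c[i, j, k]`
#' giving the number of individuals whose first SNP has genotype `i - 1`,
#' second SNP has genotype `j - 1` (0 = homozygous major, 1 = heterozygous,
#' 2 = homozygous minor) and phenotype `k - 1` (0/1). It is the sufficient
#' statistic for every interaction measure handled by this package.
#'
#' @param counts a 3x3x2 array (or something coercible to one) of
#'   non-negative integers, indexed (SNP1, SNP2, phenotype).
#' @return an object of class `count_table`: the integer array with a
#'   `total` attribute equal to the number of individuals tallied.
#' @examples
#' x <- array(0L, c(3, 3, 2))
#' x[1, 1, 1] <- 5L; x[2, 3, 2] <- 3L
#' count_table(x)
#' @export
count_table <- function(counts) {
  a <- suppressWarnings(array(as.numeric(counts), dim = c(3L, 3L, 2L)))
  if (length(counts) != 18L) {
    stop("`counts` must have exactly 18 entries (3x3x2)", call. = FALSE)
  }
  if (anyNA(a) || any(a < 0) || any(a != floor(a))) {
    stop("count table entries must be non-negative integers", call. = FALSE)
  }
  a <- array(as.integer(a), dim = c(3L, 3L, 2L),
             dimnames = list(snp1 = 0:2, snp2 = 0:2, phenotype = 0:1))
  structure(a, total = sum(a), class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat("count table (3 x 3 x 2),", attr(x, "total"), "individuals\n")
  cat("phenotype = 0:\n")
  print(unclass(x)[, , 1L])
  cat("phenotype = 1:\n")
  print(unclass(x)[, , 2L])
  invisible(x)
}

is_count_table <- function(x) inherits(x, "count_table")

as_count_table <- function(x) {
  if (is_count_table(x)) x else count_table(x)
}

validate_genotype_column <- function(x, name) {
  x <- as.integer(x)
  bad <- !is.na(x) & !(x %in% 0:2)
  if (any(bad)) {
    stop(sprintf("`%s` contains values outside {0, 1, 2, NA} at positions: %s",
                 name, paste(head(which(bad), 5L), collapse = ", ")),
         call. = FALSE)
  }
  x
}

validate_phenotype <- function(x) {
  x <- as.integer(x)
  bad <- !is.na(x) & !(x %in% 0:1)
  if (any(bad)) {
    stop(sprintf("`phenotype` contains values outside {0, 1, NA} at positions: %s",
                 paste(head(which(bad), 5L), collapse = ", ")),
         call. = FALSE)
  }
  x
}

#' Tally a genotype pair and a phenotype into a count table
#'
#' Counts individuals into the 3x3x2 cells indexed by (SNP1, SNP2,
#' phenotype). Individuals missing (`NA`) in any of the three variables are
#' dropped (complete-case per tuple), so the table total equals the number
#' of complete individuals.
#'
#' @param snp1,snp2 integer vectors of genotypes in \{0, 1, 2\} (`NA`
#'   allowed), additive minor-allele coding.
#' @param phenotype integer vector of case/control labels in \{0, 1\}
#'   (`NA` allowed).
#' @return a [count_table()].
#' @examples
#' build_count_table(c(0, 0, 1, 1, 2, 0), c(0, 0, 2, 2, 1, 0),
#'                   c(0, 1, 0, 0, 1, 0))
#' @export
build_count_table <- function(snp1, snp2, phenotype) {
  if (length(snp1) != length(snp2) || length(snp1) != length(phenotype)) {
    stop("`snp1`, `snp2` and `phenotype` must have the same length",
         call. = FALSE)
  }
  snp1 <- validate_genotype_column(snp1, "snp1")
  snp2 <- validate_genotype_column(snp2, "snp2")
  phenotype <- validate_phenotype(phenotype)
  keep <- !(is.na(snp1) | is.na(snp2) | is.na(phenotype))
  code <- 1L + snp1[keep] + 3L * snp2[keep] + 9L * phenotype[keep]
  count_table(tabulate(code, nbins = 18L))
}

#' Permutation-invariant margins of a count table
#'
#' Extracts the quantities that are unchanged by any permutation of the
#' phenotype labels: the genotype cell counts `n_ij` (summed over
#' phenotype), the phenotype-0 total `n_0`, and the cohort size `n`. These
#' three margins fully parameterize the permutation null of the table.
#'
#' @param table a [count_table()].
#' @return an object of class `genotype_margins`: a list with elements
#'   `n_ij` (3x3 integer matrix), `n_0`, and `n`.
#' @examples
#' tab <- build_count_table(c(0, 1, 1), c(0, 2, 2), c(0, 0, 1))
#' compute_margins(tab)
#' @export
compute_margins <- function(table) {
  table <- as_count_table(table)
  a <- unclass(table)
  n_ij <- a[, , 1L] + a[, , 2L]
  structure(list(n_ij = n_ij, n_0 = sum(a[, , 1L]), n = sum(a)),
            class = "genotype_margins")
}

#' @export
print.genotype_margins <- function(x, ...) {
  cat("genotype margins: n =", x$n, ", n_0 =", x$n_0, "\n")
  print(x$n_ij)
  invisible(x)
}

# Rebuild the individual-level multiset a count table summarizes: a vector
# of genotype-cell codes (1..9) and a phenotype label vector. Sufficient
# for naive label permutation, which only needs the multiset, not the
# original ordering.
expand_count_table <- function(table) {
  a <- unclass(as_count_table(table))
  cell0 <- rep.int(1:9, as.vector(a[, , 1L]))
  cell1 <- rep.int(1:9, as.vector(a[, , 2L]))
  list(cell = c(cell0, cell1),
       phenotype = rep(c(0L, 1L), c(length(cell0), length(cell1))))
}
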