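#' Read a genotype TSV file
#'
#' Tab-separated file with a header row of SNP identifiers, a first
#' column of sample identifiers, and body entries in \{0, 1, 2, NA\}
#' (additive minor-allele coding). Out-of-domain entries are rejected
#' with the offending line number, never coerced.
#'
#' @param path file path.
#' @return integer genotype matrix with sample row names and SNP column
#'   names; missing entries are `NA`.
#' @export
read_genotype_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- read.table(path, header = TRUE, sep = "\t", colClasses = "character",
                  check.names = FALSE, na.strings = character())
  if (ncol(d) < 2L) {
    stop("genotype TSV needs a sample-id column plus at least one SNP column",
         call. = FALSE)
  }
  ids <- d[[1L]]
  body <- as.matrix(d[, -1L, drop = FALSE])
  ok <- matrix(body %in% c("0", "1", "2", "NA"), nrow = nrow(body))
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "invalid genotype '%s' at line %d (sample '%s', SNP '%s'); expected 0, 1, 2 or NA",
      body[bad[1L], bad[2L]], bad[1L] + 1L, ids[bad[1L]],
      colnames(body)[bad[2L]]), call. = FALSE)
  }
  g <- matrix(suppressWarnings(as.integer(body)), nrow = nrow(body),
              dimnames = list(ids, colnames(body)))
  g
}

#' Write a genotype matrix as TSV
#'
#' Inverse of [read_genotype_tsv()]; integer entries round-trip exactly.
#'
#' @param genotypes integer matrix in \{0, 1, 2, NA\}.
#' @param path output path.
#' @param id_column header name of the sample-id column.
#' @return `path`, invisibly.
#' @export
write_genotype_tsv <- function(genotypes, path, id_column = "sample_id") {
  genotypes <- as.matrix(genotypes)
  apply(genotypes, 2L, validate_genotype_column, name = "genotypes")
  ids <- rownames(genotypes) %||% paste0("ind", seq_len(nrow(genotypes)))
  snps <- colnames(genotypes) %||% paste0("snp", seq_len(ncol(genotypes)))
  d <- data.frame(ids, genotypes, check.names = FALSE)
  colnames(d) <- c(id_column, snps)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read / write a phenotype TSV file
#'
#' Single-column tab-separated file with a header line and body entries
#' in \{0, 1, NA\}.
#'
#' @param path file path.
#' @return integer vector in \{0, 1, NA\}.
#' @export
read_phenotype_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- read.table(path, header = TRUE, sep = "\t", colClasses = "character",
                  na.strings = character())
  v <- d[[1L]]
  ok <- v %in% c("0", "1", "NA")
  if (!all(ok)) {
    bad <- which(!ok)[1L]
    stop(sprintf("invalid phenotype '%s' at line %d; expected 0, 1 or NA",
                 v[bad], bad + 1L), call. = FALSE)
  }
  suppressWarnings(as.integer(v))
}

#' @rdname read_phenotype_tsv
#' @param phenotype integer vector in \{0, 1, NA\}.
#' @param header column header to write.
#' @export
write_phenotype_tsv <- function(phenotype, path, header = "phenotype") {
  phenotype <- validate_phenotype(phenotype)
  d <- data.frame(x = phenotype)
  colnames(d) <- header
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read a PLINK `.raw` additive-coding file
#'
#' Whitespace-delimited export of `plink --recode A`: header columns
#' `FID IID PAT MAT SEX PHENOTYPE` followed by one column per SNP with
#' genotypes coded 0/1/2 (count of a designated allele) and `NA` for
#' missing. The case/control phenotype is translated at this boundary:
#' 1 (control) becomes 0, 2 (case) becomes 1, and -9/0/NA become
#' missing. Quantitative phenotypes are rejected.
#'
#' @param path file path.
#' @return list with `genotypes` (integer matrix, rows named `FID_IID`)
#'   and `phenotype` (integer vector in \{0, 1, NA\}).
#' @export
read_plink_raw <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- read.table(path, header = TRUE, colClasses = "character",
                  check.names = FALSE, na.strings = character())
  fixed <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (ncol(d) < 7L || !identical(colnames(d)[1:6], fixed)) {
    stop(".raw header must start with: ", paste(fixed, collapse = " "),
         call. = FALSE)
  }
  ph_raw <- d$PHENOTYPE
  ph <- rep(NA_integer_, length(ph_raw))
  ph[ph_raw == "1"] <- 0L
  ph[ph_raw == "2"] <- 1L
  unknown <- !(ph_raw %in% c("1", "2", "-9", "0", "NA"))
  if (any(unknown)) {
    stop(sprintf(
      "unsupported PHENOTYPE value '%s' at line %d; only case/control coding (1/2, missing -9/0/NA) is supported",
      ph_raw[which(unknown)[1L]], which(unknown)[1L] + 1L), call. = FALSE)
  }
  body <- as.matrix(d[, -(1:6), drop = FALSE])
  ok <- matrix(body %in% c("0", "1", "2", "NA"), nrow = nrow(body))
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1L, ]
    stop(sprintf("invalid genotype '%s' at line %d (SNP '%s')",
                 body[bad[1L], bad[2L]], bad[1L] + 1L,
                 colnames(body)[bad[2L]]), call. = FALSE)
  }
  g <- matrix(suppressWarnings(as.integer(body)), nrow = nrow(body),
              dimnames = list(paste(d$FID, d$IID, sep = "_"),
                              colnames(body)))
  list(genotypes = g, phenotype = ph)
}

#' Read / write a count table as JSON
#'
#' JSON object with fields `layer0` and `layer1`, each a 3x3 integer
#' matrix (rows = SNP1 genotype, columns = SNP2 genotype), for phenotype
#' values 0 and 1 respectively. Integers round-trip exactly.
#'
#' @param path file path.
#' @return a [count_table()].
#' @examples
#' tab <- example_count_table()
#' f <- tempfile(fileext = ".json")
#' write_count_table(tab, f)
#' identical(unclass(read_count_table(f)), unclass(tab))
#' @export
read_count_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  j <- jsonlite::fromJSON(path)
  if (!all(c("layer0", "layer1") %in% names(j))) {
    stop("count-table JSON must have fields 'layer0' and 'layer1'",
         call. = FALSE)
  }
  l0 <- as.matrix(j$layer0)
  l1 <- as.matrix(j$layer1)
  if (!all(dim(l0) == c(3L, 3L)) || !all(dim(l1) == c(3L, 3L))) {
    stop("count-table layers must be 3x3", call. = FALSE)
  }
  tab <- count_table(array(c(l0, l1), dim = c(3L, 3L, 2L)))
  if (attr(tab, "total") < 1L) {
    stop("count table is empty (total = 0)", call. = FALSE)
  }
  tab
}

#' @rdname read_count_table
#' @param table a [count_table()].
#' @export
write_count_table <- function(table, path) {
  table <- as_count_table(table)
  a <- unclass(table)
  jsonlite::write_json(
    list(layer0 = matrix(as.integer(a[, , 1L]), 3L, 3L),
         layer1 = matrix(as.integer(a[, , 2L]), 3L, 3L)),
    path, matrix = "rowmajor"
  )
  invisible(path)
}

#' Write scan results as TSV
#'
#' @param records data.frame from [scan_pairs()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scan_tsv <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
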