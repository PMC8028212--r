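# Per-cell two-sample comparison between two ensembles of phenotype-0
# counts. Cells whose pooled sample is constant (e.g. empty genotype
# cells) admit no distribution test and are reported NA.
cellwise_es_pvalues <- function(layer0_a, layer0_b) {
  vapply(1:9, function(cell) {
    a <- layer0_a[, cell]
    b <- layer0_b[, cell]
    pooled <- c(a, b)
    if (length(unique(pooled)) == 1L) return(NA_real_)
    tryCatch(epps_singleton_test(a, b)$p.value,
             error = function(e) NA_real_)
  }, numeric(1))
}

#' One equivalence trial: transform vs naive permutation
#'
#' Generates a null count table from the Hardy-Weinberg simulator, samples
#' `n_perm` permuted tables with both the direct hypergeometric transform
#' and naive label shuffling, and compares the two ensembles cell by cell
#' with Epps-Singleton tests on the phenotype-0 counts. Under the claim
#' that the transform reproduces the permutation null exactly, the nine
#' p-values are uniform.
#'
#' @param n cohort size.
#' @inheritParams generate_tuple_count_table
#' @param n_perm permuted tables per method (>= 100 for reasonable test
#'   power).
#' @param method sampler under test: `"transform"` (the package's
#'   algorithm) or `"binomial"` (the deliberately wrong
#'   independent-binomial negative control, see [binomial_ensemble()]).
#' @inheritParams generate_snp
#' @return a list of class `equivalence_trial`: `params` (n, maf,
#'   zero_prob), `p_values` (nine per-cell p-values, NA where a cell is
#'   degenerate), `n_applicable`, `method`.
#' @examples
#' run_equivalence_trial(n = 2000, n_perm = 200, seed = 1)$p_values
#' @export
run_equivalence_trial <- function(n = 10000, maf = 0.45, zero_prob = 0.66,
                                  n_perm = 1000,
                                  method = c("transform", "binomial"),
                                  seed = NULL) {
  method <- match.arg(method)
  n <- check_count(n, "n")
  n_perm <- check_count(n_perm, "n_perm")
  if (n_perm < 100L) {
    stop("`n_perm` must be at least 100 for the equivalence test to have power",
         call. = FALSE)
  }
  with_seed(seed, {
    snp1 <- generate_snp(n, maf)
    snp2 <- generate_snp(n, maf)
    phen <- generate_phenotype(n, zero_prob)
    tab <- build_count_table(snp1, snp2, phen)
    cand <- switch(method,
      transform = sample_ensemble(tab, n_perm),
      binomial = binomial_ensemble(tab, n_perm)
    )
    ref <- naive_ensemble(snp1 = snp1, snp2 = snp2, phenotype = phen,
                          n_perm = n_perm)
    pv <- cellwise_es_pvalues(cand$layer0, ref$layer0)
    structure(list(params = list(n = n, maf = maf, zero_prob = zero_prob),
                   p_values = pv, n_applicable = sum(!is.na(pv)),
                   method = method),
              class = "equivalence_trial")
  })
}

#' Equivalence validation suite over random generator parameters
#'
#' Repeats [run_equivalence_trial()] `n_trials` times with the minor
#' allele frequency and phenotype-0 probability drawn independently and
#' uniformly from (0.01, 0.99), pooling all applicable per-cell
#' Epps-Singleton p-values. If the sampler under test reproduces the
#' permutation null, the pooled p-values are uniform on (0, 1) — check
#' with [uniformity_check()] or a QQ plot ([plot_pvalue_qq()]).
#'
#' Defaults are sized for routine validation (100 trials of 200
#' permutations); increase `n_trials` / `n_perm` (e.g. 1000 and 1000,
#' giving 9000 pooled p-values when all cells are populated) for a
#' full-scale run.
#'
#' @param n_trials number of independent trials.
#' @inheritParams run_equivalence_trial
#' @return an object of class `equivalence_suite`: a data.frame with one
#'   row per trial x cell (`trial`, `cell_i`, `cell_j`, `maf`,
#'   `zero_prob`, `p_value`), plus attributes `n`, `n_perm`, `method`.
#' @examples
#' \donttest{
#' suite <- run_equivalence_suite(n_trials = 10, n = 2000, n_perm = 200,
#'                                seed = 1)
#' uniformity_check(suite)
#' }
#' @export
run_equivalence_suite <- function(n_trials = 100, n = 10000, n_perm = 200,
                                  method = c("transform", "binomial"),
                                  seed = NULL) {
  method <- match.arg(method)
  n_trials <- check_count(n_trials, "n_trials")
  with_seed(seed, {
    rows <- vector("list", n_trials)
    for (trial in seq_len(n_trials)) {
      maf <- runif(1, 0.01, 0.99)
      q <- runif(1, 0.01, 0.99)
      tr <- run_equivalence_trial(n = n, maf = maf, zero_prob = q,
                                  n_perm = n_perm, method = method)
      rows[[trial]] <- data.frame(
        trial = trial,
        cell_i = rep(0:2, times = 3),
        cell_j = rep(0:2, each = 3),
        maf = maf, zero_prob = q,
        p_value = tr$p_values
      )
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    structure(out, n = n, n_perm = n_perm, method = method,
              class = c("equivalence_suite", "data.frame"))
  })
}

#' Kolmogorov-Smirnov uniformity check of pooled equivalence p-values
#'
#' Applies a one-sample KS test against U(0, 1) to the applicable pooled
#' p-values of an equivalence suite. A small KS p-value means the sampler
#' under test is distinguishable from naive permutation.
#'
#' @param suite an `equivalence_suite` (or a numeric vector of
#'   p-values).
#' @return a list: `n_pvalues`, `ks_statistic`, `ks_p_value`.
#' @export
uniformity_check <- function(suite) {
  pv <- if (is.data.frame(suite)) suite$p_value else as.numeric(suite)
  pv <- pv[!is.na(pv)]
  if (length(pv) < 10L) {
    stop("need at least 10 applicable p-values", call. = FALSE)
  }
  ks <- suppressWarnings(ks.test(pv, "punif")) # ties expected: counts are discrete
  list(n_pvalues = length(pv),
       ks_statistic = unname(ks$statistic),
       ks_p_value = ks$p.value)
}

#' Overlay the transform and naive null distributions for one table
#'
#' Samples `n_perm` permuted tables with both methods from the same count
#' table and collects, for each of the nine genotype cells, the two
#' empirical distributions of the phenotype-0 count, together with the
#' two null distributions of a summary measure (multi-information by
#' default). Use [plot_overlay()] to render the histograms and
#' [write_overlay_tsv()] to export binned counts.
#'
#' @inheritParams sample_ensemble
#' @inheritParams apply_measure
#' @return an object of class `distribution_overlay`: list with
#'   `layer0_transform`, `layer0_naive` (`n_perm` x 9 matrices),
#'   `measure_transform`, `measure_naive` (numeric vectors),
#'   `measure_name`, `es_p_values` (nine per-cell p-values plus one for
#'   the measure, named), and `margins`.
#' @examples
#' \donttest{
#' ov <- overlay_distributions(example_count_table(), n_perm = 1000,
#'                             seed = 1)
#' ov$es_p_values
#' }
#' @export
overlay_distributions <- function(table, n_perm = 1000,
                                  measure = "multi_information",
                                  seed = NULL) {
  table <- as_count_table(table)
  n_perm <- check_count(n_perm, "n_perm")
  if (n_perm < 1000L) {
    stop("`n_perm` must be at least 1000 for stable overlay histograms",
         call. = FALSE)
  }
  m <- resolve_measure(measure)
  with_seed(seed, {
    et <- sample_ensemble(table, n_perm)
    en <- naive_ensemble(table = table, n_perm = n_perm)
    pv_cells <- cellwise_es_pvalues(et$layer0, en$layer0)
    mt <- ensemble_measure(et, m$fn)
    mn <- ensemble_measure(en, m$fn)
    pv_meas <- if (length(unique(c(mt, mn))) == 1L) NA_real_ else {
      tryCatch(epps_singleton_test(mt, mn)$p.value,
               error = function(e) NA_real_)
    }
    names(pv_cells) <- paste0("c", rep(0:2, times = 3), rep(0:2, each = 3), "0")
    structure(list(layer0_transform = et$layer0, layer0_naive = en$layer0,
                   measure_transform = mt, measure_naive = mn,
                   measure_name = m$name,
                   es_p_values = c(pv_cells, measure = pv_meas),
                   margins = et$margins),
              class = "distribution_overlay")
  })
}

overlay_long <- function(overlay) {
  cells <- names(overlay$es_p_values)[1:9]
  cell_df <- do.call(rbind, lapply(1:9, function(cell) {
    data.frame(
      panel = cells[cell],
      method = rep(c("transform", "naive"),
                   c(nrow(overlay$layer0_transform),
                     nrow(overlay$layer0_naive))),
      value = c(overlay$layer0_transform[, cell],
                overlay$layer0_naive[, cell])
    )
  }))
  meas_df <- data.frame(
    panel = overlay$measure_name,
    method = rep(c("transform", "naive"),
                 c(length(overlay$measure_transform),
                   length(overlay$measure_naive))),
    value = c(overlay$measure_transform, overlay$measure_naive)
  )
  rbind(cell_df, meas_df)
}

#' Write binned overlay distributions to TSV
#'
#' One row per (panel, method, bin): the nine phenotype-0 cell counts and
#' the summary measure, for both sampling methods.
#'
#' @param overlay a `distribution_overlay`.
#' @param path output TSV path.
#' @param bins number of histogram bins for the (continuous) measure
#'   panel; integer cell counts are binned at unit width.
#' @return `path`, invisibly.
#' @export
write_overlay_tsv <- function(overlay, path, bins = 50) {
  long <- overlay_long(overlay)
  out <- do.call(rbind, lapply(split(long, long$panel), function(d) {
    if (d$panel[1] == overlay$measure_name) {
      brk <- seq(min(d$value), max(d$value), length.out = bins + 1L)
      if (length(unique(brk)) == 1L) brk <- c(brk[1], brk[1] + 1e-9)
      mid <- (brk[-1] + brk[-length(brk)]) / 2
      do.call(rbind, lapply(split(d, d$method), function(dm) {
        h <- graphics::hist(dm$value, breaks = brk, plot = FALSE)
        data.frame(panel = d$panel[1], method = dm$method[1],
                   bin_mid = mid, count = h$counts)
      }))
    } else {
      rng <- range(d$value)
      mids <- seq(rng[1], rng[2])
      do.call(rbind, lapply(split(d, d$method), function(dm) {
        data.frame(panel = d$panel[1], method = dm$method[1],
                   bin_mid = mids,
                   count = tabulate(dm$value - rng[1] + 1L,
                                    nbins = length(mids)))
      }))
    }
  }))
  rownames(out) <- NULL
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Plot overlaid null distributions
#'
#' Renders the per-cell and measure histograms of a
#' [overlay_distributions()] result, with the two methods
#' semi-transparent so agreement shows as near-complete overlap.
#'
#' @param overlay a `distribution_overlay`.
#' @param path optional output file (`.png` or `.svg`); if `NULL` the
#'   ggplot object is returned unrendered.
#' @param width,height device size in inches.
#' @return the ggplot object, invisibly if written to file.
#' @export
plot_overlay <- function(overlay, path = NULL, width = 9, height = 8) {
  long <- overlay_long(overlay)
  p <- ggplot2::ggplot(long, ggplot2::aes(x = value, fill = method)) +
    ggplot2::geom_histogram(position = "identity", alpha = 0.5, bins = 40) +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = "value", y = "count",
                  title = "Permutation null: transform vs naive") +
    ggplot2::theme_minimal()
  if (is.null(path)) return(p)
  save_plot(p, path, width, height)
  invisible(p)
}

#' QQ plot of pooled equivalence p-values against U(0, 1)
#'
#' @param suite an `equivalence_suite` or numeric vector of p-values.
#' @inheritParams plot_overlay
#' @return the ggplot object, invisibly if written to file.
#' @export
plot_pvalue_qq <- function(suite, path = NULL, width = 5, height = 5) {
  pv <- if (is.data.frame(suite)) suite$p_value else as.numeric(suite)
  pv <- sort(pv[!is.na(pv)])
  d <- data.frame(theoretical = stats::ppoints(length(pv)), observed = pv)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = theoretical, y = observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey50") +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(x = "uniform quantiles", y = "observed p-values",
                  title = "Equivalence p-values vs U(0,1)") +
    ggplot2::theme_minimal()
  if (is.null(path)) return(p)
  save_plot(p, path, width, height)
  invisible(p)
}

save_plot <- function(p, path, width, height) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png(path, width = width, height = height, units = "in", res = 150),
    svg = svg(path, width = width, height = height),
    stop("unsupported plot format: ", ext, call. = FALSE)
  )
  on.exit(dev.off())
  print(p)
}
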