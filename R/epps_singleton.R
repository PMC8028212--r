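#' Epps-Singleton two-sample test
#'
#' Tests the null hypothesis that two samples come from the same
#' distribution, by comparing the empirical characteristic functions of
#' the samples at the evaluation points `t` (scaled by the
#' semi-interquartile range of the pooled sample). Unlike the
#' Kolmogorov-Smirnov test it is valid for discrete data, which makes it
#' the right tool for comparing ensembles of integer cell counts. The
#' statistic is asymptotically chi-squared; the standard small-sample
#' correction is applied when both samples have fewer than 25
#' observations.
#'
#' @param x,y numeric vectors, at least five observations each.
#' @param t positive characteristic-function evaluation points; the
#'   default `c(0.4, 0.8)` is the conventional omnibus choice.
#' @return an object of class `htest` with `statistic` (W2), `parameter`
#'   (chi-squared df) and `p.value`.
#' @examples
#' set.seed(1)
#' epps_singleton_test(rbinom(100, 20, 0.4), rbinom(100, 20, 0.4))$p.value
#' @export
epps_singleton_test <- function(x, y, t = c(0.4, 0.8)) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (anyNA(x) || anyNA(y)) stop("samples must not contain NA", call. = FALSE)
  nx <- length(x)
  ny <- length(y)
  if (nx < 5L || ny < 5L) {
    stop("both samples need at least 5 observations", call. = FALSE)
  }
  if (any(t <= 0)) stop("`t` must contain positive values only", call. = FALSE)
  n <- nx + ny

  # scale evaluation points by the semi-interquartile range of the pool
  sigma <- stats::IQR(c(x, y), type = 7) / 2
  if (sigma <= 0) {
    stop("pooled sample has zero interquartile range; test not applicable",
         call. = FALSE)
  }
  ts <- t / sigma

  g <- function(v) cbind(cos(outer(v, ts)), sin(outer(v, ts)))
  gx <- g(x)
  gy <- g(y)
  cov_x <- cov(gx) * (nx - 1) / nx # biased covariance estimates
  cov_y <- cov(gy) * (ny - 1) / ny
  est_cov <- (n / nx) * cov_x + (n / ny) * cov_y

  # Moore-Penrose pseudo-inverse; df is the rank of the covariance
  sv <- svd(est_cov)
  tol <- max(dim(est_cov)) * .Machine$double.eps * max(sv$d)
  keep <- sv$d > tol
  r <- sum(keep)
  if (r < 1L) {
    stop("estimated covariance matrix has rank 0; test not applicable",
         call. = FALSE)
  }
  inv_d <- ifelse(keep, 1 / sv$d, 0)
  est_cov_inv <- sv$v %*% (inv_d * t(sv$u))

  g_diff <- colMeans(gx) - colMeans(gy)
  w <- as.numeric(n * (g_diff %*% est_cov_inv %*% g_diff))
  if (max(nx, ny) < 25L) {
    w <- w / (1 + n^(-0.45) + 10.1 * (nx^(-1.7) + ny^(-1.7)))
  }
  structure(list(
    statistic = c(W2 = w),
    parameter = c(df = r),
    p.value = pchisq(w, df = r, lower.tail = FALSE),
    method = "Epps-Singleton two-sample test",
    data.name = paste(deparse(substitute(x)), "and", deparse(substitute(y)))
  ), class = "htest")
}
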