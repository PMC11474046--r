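#' Two-sample Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples, as used throughout the
#' package to compare per-cell quantities (average growth rate, G1 duration)
#' between swarmer and stalked progenies or between strains. Ties are handled
#' by midranks. The exact null distribution is enumerated when
#' `n1 + n2 <= 12` and the pooled sample is tie-free; otherwise the normal
#' approximation with tie correction is used. P-values are two-sided.
#'
#' @param x,y Numeric vectors, each with at least one observation.
#' @return A `test_result` list: `statistic` (the U statistic for `x`),
#'   `p_value`, `n1`, `n2`, `method` (`"exact"` or `"asymptotic"`).
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))$p_value  # 1/3 by exact enumeration
#' @export
mann_whitney_u <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 1L || length(y) < 1L) stopf("both samples must be non-empty")
  if (anyNA(x) || anyNA(y)) stopf("samples must not contain NA")
  n1 <- length(x); n2 <- length(y)
  no_ties <- !anyDuplicated(c(x, y))
  exact <- (n1 + n2) <= 12L && no_ties
  ht <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            alternative = "two.sided"))
  test_result(statistic = unname(ht$statistic), p_value = ht$p.value,
              n1 = n1, n2 = n2,
              method = if (exact) "exact" else "asymptotic")
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Supremum distance between the two empirical CDFs with the asymptotic
#' two-sided p-value, used for distribution-level comparisons of aligned
#' growth-rate values between strains.
#'
#' @inheritParams mann_whitney_u
#' @return A `test_result` list with the D statistic.
#' @export
ks_two_sample <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 1L || length(y) < 1L) stopf("both samples must be non-empty")
  if (anyNA(x) || anyNA(y)) stopf("samples must not contain NA")
  ht <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  test_result(statistic = unname(ht$statistic), p_value = ht$p.value,
              n1 = length(x), n2 = length(y), method = "asymptotic")
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks; `NA` with a warning when either vector is
#' constant (the correlation is undefined).
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return Correlation coefficient in `[-1, 1]`, or `NA`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  if (length(x) < 2L) stopf("need at least 2 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input: Spearman correlation undefined", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}

#' Percentile bootstrap confidence interval for a mean
#'
#' Nonparametric bootstrap of the sample mean with a percentile interval.
#' Deterministic for a fixed `seed`.
#'
#' @param x Numeric vector, `n >= 2`.
#' @param n_boot Number of bootstrap resamples.
#' @param alpha Two-sided miscoverage; the interval is the
#'   (`alpha/2`, `1 - alpha/2`) percentile pair.
#' @param seed Integer seed for the resampling stream.
#' @return Named numeric vector `c(mean, lo, hi)`.
#' @export
bootstrap_ci_mean <- function(x, n_boot = 1000L, alpha = 0.05, seed = 1L) {
  x <- as.numeric(x)
  if (length(x) < 2L) stopf("need n >= 2 for a bootstrap CI")
  if (anyNA(x)) stopf("x must not contain NA")
  n <- length(x)
  means <- with_seed(seed, {
    idx <- sample.int(n, n * n_boot, replace = TRUE)
    colMeans(matrix(x[idx], nrow = n))
  })
  qs <- stats::quantile(means, c(alpha / 2, 1 - alpha / 2), names = FALSE,
                        type = 7)
  c(mean = mean(x), lo = qs[1], hi = qs[2])
}

test_result <- function(statistic, p_value, n1, n2, method) {
  structure(list(statistic = statistic, p_value = p_value,
                 n1 = n1, n2 = n2, method = method),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("Two-sample test (%s): statistic = %.6g, p = %.4g (n1 = %d, n2 = %d)\n",
              x$method, x$statistic, x$p_value, x$n1, x$n2))
  invisible(x)
}
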