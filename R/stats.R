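# The small statistics layer used for group comparisons: permutation
# Wilcoxon rank-sum, Spearman correlation, Benjamini-Hochberg adjustment,
# and median/IQR summaries.

#' Two-sided Wilcoxon rank-sum test by permutation
#'
#' The observed statistic is the rank sum of `x` in the pooled sample
#' (average ranks for ties). Group labels are permuted `n_perm` times; the
#' two-sided p-value is (1 + #permutations at least as extreme as the
#' observed deviation from the null expectation) / (n_perm + 1), so p is
#' never 0 and is bounded below by 1/(n_perm + 1).
#'
#' @param x,y Numeric vectors (each non-empty).
#' @param n_perm Number of permutations; default 10000.
#' @param seed Integer seed; the result is deterministic given the seed.
#' @return List (class `perm_test`): statistic (rank sum of x), p_value,
#'   n_permutations, seed.
#' @export
permutation_wilcoxon <- function(x, y, n_perm = 10000, seed = 1) {
  abort_if(length(x) == 0 || length(y) == 0,
           "both groups must be non-empty")
  pooled <- c(x, y)
  n <- length(pooled)
  nx <- length(x)
  r <- rank(pooled)
  obs <- sum(r[seq_len(nx)])
  expected <- nx * (n + 1) / 2
  obs_dev <- abs(obs - expected)
  perm_dev <- with_seed(seed, {
    vapply(seq_len(n_perm),
           function(i) abs(sum(r[sample.int(n, nx)]) - expected),
           numeric(1))
  })
  p <- (1 + sum(perm_dev >= obs_dev)) / (n_perm + 1)
  structure(list(statistic = obs, p_value = p, n_permutations = n_perm,
                 seed = seed),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat("permutation Wilcoxon rank-sum: W = ", x$statistic, ", p = ",
      format(x$p_value), " (", x$n_permutations, " permutations, seed ",
      x$seed, ")\n", sep = "")
  invisible(x)
}

#' Spearman rank correlation (average ranks for ties)
#'
#' @param x,y Numeric vectors of equal length.
#' @return rho in [-1, 1]; NA when either vector has zero rank variance.
#' @export
spearman <- function(x, y) {
  abort_if(length(x) != length(y), "x and y must have equal length")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2 || stats::sd(rank(x)) == 0 || stats::sd(rank(y)) == 0) {
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement;
#' adjusted values never fall below the raw p and never exceed 1.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p_values) {
  abort_if(any(is.na(p_values) | p_values <= 0 | p_values > 1),
           "p-values must lie in (0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Median and interquartile range
#'
#' Linear-interpolation (type 7) quantiles.
#'
#' @param values Numeric vector (non-empty).
#' @return Named vector c(median, q1, q3).
#' @export
median_iqr <- function(values) {
  abort_if(length(values) == 0, "empty input")
  q <- stats::quantile(values, c(0.5, 0.25, 0.75), type = 7, names = FALSE,
                       na.rm = TRUE)
  c(median = q[1], q1 = q[2], q3 = q[3])
}
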