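#' Dice similarity coefficient between two masks
#'
#' `2 |A n B| / (|A| + |B|)`: 1 for identical non-empty masks, 0 for
#' disjoint ones. Undefined (error) when both masks are empty.
#'
#' @param a,b [binary_mask()] objects on the same grid.
#' @return Ratio in \[0, 1\].
#' @export
dsc <- function(a, b) {
  stopifnot(inherits(a, "binary_mask"), inherits(b, "binary_mask"))
  stop_if_grid_mismatch(a, b)
  na <- sum(a$voxels); nb <- sum(b$voxels)
  if (na + nb == 0L) stop("DSC undefined: both masks are empty")
  2 * sum(a$voxels & b$voxels) / (na + nb)
}

#' Two-way random single-score intraclass correlation, ICC(2,1)
#'
#' Absolute-agreement single-measurement ICC from the two-way random-effects
#' model (Shrout & Fleiss ICC(2,1); McGraw & Wong ICC(A,1)): with mean
#' squares for rows (subjects) `MSR`, columns (conditions) `MSC` and error
#' `MSE`,
#' \deqn{ICC = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE)).}
#' The 95% confidence interval uses the F-based Shrout-Fleiss procedure with
#' Satterthwaite degrees of freedom for the lower/upper bounds; bounds are
#' clipped to \[-1, 1\].
#'
#' Rows containing missing values are dropped (complete-case) before the
#' analysis. A table with zero total variance (all values identical) returns
#' ICC 1 with degenerate interval \[1, 1\] and a warning.
#'
#' @param values An `n x k` numeric matrix: rows are subjects, columns
#'   repeated conditions (here, the two scans).
#' @param alpha Two-sided confidence level is `1 - alpha` (default 0.05).
#' @return An object of class `icc_result`: list with `icc`, `ci_low`,
#'   `ci_high`, `n_subjects`, `k_conditions`.
#' @examples
#' icc_two_way_random_single(cbind(c(1, 2, 3), c(2, 3, 4)))
#' @export
icc_two_way_random_single <- function(values, alpha = 0.05) {
  values <- as.matrix(values)
  values <- values[complete.cases(values), , drop = FALSE]
  n <- nrow(values); k <- ncol(values)
  if (k < 2) stop("need at least 2 repeated conditions")
  if (n < 3) stop("need at least 3 complete-case subjects for ICC")
  grand <- mean(values)
  rowm <- rowMeans(values)
  colm <- colMeans(values)
  sst <- sum((values - grand)^2)
  scale <- max(abs(values), 1)
  if (sst <= (1e-12 * scale)^2 * n * k) {
    warning("zero total variance: ICC degenerate at 1", call. = FALSE)
    return(new_icc_result(1, 1, 1, n, k))
  }
  msr <- k * sum((rowm - grand)^2) / (n - 1)
  msc <- n * sum((colm - grand)^2) / (k - 1)
  mse <- sum((values - outer(rowm, rep(1, k)) -
                outer(rep(1, n), colm) + grand)^2) / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))

  # F-based CI (Shrout & Fleiss 1979; McGraw & Wong 1996, ICC(A,1))
  if (mse > 0) {
    fj <- msc / mse
    vn <- (k - 1) * (n - 1) *
      (k * icc * fj + n * (1 + (k - 1) * icc) - k * icc)^2
    vd <- (n - 1) * k^2 * icc^2 * fj^2 +
      (n * (1 + (k - 1) * icc) - k * icc)^2
    v <- vn / vd
  } else {
    v <- k - 1  # limit of the Satterthwaite df as MSE -> 0
  }
  if (!is.finite(v) || v <= 0) v <- k - 1
  fl <- qf(1 - alpha / 2, n - 1, v)
  fu <- qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - fl * mse) /
    (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (fu * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * fu * msr)
  new_icc_result(icc, max(-1, min(lower, icc)), min(1, max(upper, icc)), n, k)
}

new_icc_result <- function(icc, lo, hi, n, k) {
  structure(list(icc = icc, ci_low = lo, ci_high = hi,
                 n_subjects = n, k_conditions = k),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(2,1) = %.3f  95%% CI [%.3f, %.3f]  (n = %d, k = %d)\n",
              x$icc, x$ci_low, x$ci_high, x$n_subjects, x$k_conditions))
  invisible(x)
}

#' Significance by 95% CI overlap
#'
#' Two ICC estimates are declared significantly different only when their
#' confidence intervals are strictly disjoint; intervals that touch at one
#' endpoint count as overlapping (not significant).
#'
#' @param a,b `icc_result` objects.
#' @return Logical: `TRUE` when significantly different.
#' @export
ci_overlap_significant <- function(a, b) {
  stopifnot(inherits(a, "icc_result"), inherits(b, "icc_result"))
  a$ci_high < b$ci_low || b$ci_high < a$ci_low
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided p-value for paired samples. Zero differences are dropped before
#' ranking (classical Wilcoxon handling); the exact null distribution is
#' used for up to 25 non-zero untied differences, and the normal
#' approximation with tie and continuity correction otherwise. If all
#' differences are zero the p-value is 1 with a warning.
#'
#' @param x,y Equal-length paired numeric vectors.
#' @return Two-sided p-value.
#' @export
wilcoxon_signed_rank <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  d <- y - x
  d <- d[d != 0]
  if (length(d) == 0) {
    warning("all paired differences are zero", call. = FALSE)
    return(1)
  }
  if (length(d) < 5)
    stop("need at least 5 non-zero paired differences")
  use_exact <- length(d) <= 25 && !any(duplicated(abs(d)))
  res <- suppressWarnings(
    wilcox.test(d, alternative = "two.sided", mu = 0,
                exact = use_exact, correct = TRUE))
  unname(res$p.value)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment: sorted ascending,
#' `q_i = min_{j >= i} p_j * m / j`, capped at 1, returned in input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, elementwise `>=` the input.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must be in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties; two-sided p-value by the
#' t-distribution approximation. A constant input vector has no defined rank
#' correlation and yields `NA` with a warning.
#'
#' @param x,y Equal-length numeric vectors (length >= 3).
#' @return List with `rho` and `p`.
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 pairs")
  if (var(x) == 0 || var(y) == 0) {
    warning("constant input: Spearman correlation undefined", call. = FALSE)
    return(list(rho = NA_real_, p = NA_real_))
  }
  res <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(res$estimate), p = unname(res$p.value))
}

#' Bland-Altman agreement analysis
#'
#' Bias is the mean of the paired differences `y - x`; the limits of
#' agreement are `bias +/- 1.96 * SD` of the differences (sample SD,
#' divisor n - 1).
#'
#' @param x,y Equal-length paired numeric vectors (length >= 2).
#' @return An object of class `bland_altman_result`: list with `bias`,
#'   `loa_low`, `loa_high`, `n`.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2) stop("need at least 2 pairs")
  d <- y - x
  bias <- mean(d)
  s <- sd(d)
  structure(list(bias = bias, loa_low = bias - 1.96 * s,
                 loa_high = bias + 1.96 * s, n = length(d)),
            class = "bland_altman_result")
}

#' @export
print.bland_altman_result <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias %.4g, limits of agreement [%.4g, %.4g], n = %d\n",
              x$bias, x$loa_low, x$loa_high, x$n))
  invisible(x)
}

#' Median percent difference between paired scans
#'
#' Median over subjects of `100 * (scan2 - scan1) / scan1`, the summary used
#' to report systematic volume change between two scans.
#'
#' @param scan1,scan2 Equal-length positive-denominator paired values.
#' @return Percentage.
#' @export
percent_median_difference <- function(scan1, scan2) {
  if (length(scan1) != length(scan2)) stop("inputs must have equal length")
  if (any(scan1 <= 0)) stop("scan1 values must be positive")
  median(100 * (scan2 - scan1) / scan1)
}
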