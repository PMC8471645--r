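#' Quality-score-based cohort filter
#'
#' A subject is excluded when its quality score is below the threshold on
#' scan 1 or scan 2 (or both); the comparison is strict, so a score exactly
#' at the threshold is kept.
#'
#' @param subject_ids Character or integer vector of subject identifiers.
#' @param scores_scan1,scores_scan2 Quality scores in \[0, 100\], one per
#'   subject per scan.
#' @param threshold Exclusion threshold (default 85).
#' @return List with `kept` and `excluded` subject id vectors (disjoint,
#'   union equals all subjects).
#' @export
apply_quality_filter <- function(subject_ids, scores_scan1, scores_scan2,
                                 threshold = 85) {
  n <- length(subject_ids)
  if (length(scores_scan1) != n || length(scores_scan2) != n)
    stop("one score per subject per scan required")
  if (any(c(scores_scan1, scores_scan2) < 0 |
            c(scores_scan1, scores_scan2) > 100, na.rm = TRUE))
    stop("quality scores must be in [0, 100]")
  bad <- scores_scan1 < threshold | scores_scan2 < threshold
  bad[is.na(bad)] <- FALSE
  list(kept = subject_ids[!bad], excluded = subject_ids[bad])
}

#' Permutation test for quality-filtering improvement of the ICC
#'
#' Tests whether the ICC obtained after excluding `n_excluded` subjects by a
#' quality-control rule is higher than expected from excluding the same
#' number of subjects at random. In each run, `n_excluded` subjects (rows of
#' the measurement table; both scans removed together) are drawn uniformly
#' without replacement, the ICC is recomputed on the remainder, and the
#' count `n_ge` of permuted ICC values greater than or equal to the observed
#' one is accumulated (ties count toward `n_ge`). The improvement is
#' declared significant when fewer than 5% of runs reach the observed value
#' (`n_ge < 0.05 * runs`; with 1000 runs, fewer than 50).
#'
#' The random subject draws use R's RNG seeded from `seed`; the previous RNG
#' state is restored on exit, so results are reproducible and the caller's
#' random stream is untouched.
#'
#' @param values `n x k` measurement matrix (all subjects, before quality
#'   filtering); rows are subjects, columns scans.
#' @param n_excluded Number of subjects the quality filter excluded; must
#'   leave at least 3 subjects.
#' @param observed_icc_after ICC computed on the quality-filtered cohort.
#' @param runs Number of permutation runs (default 1000).
#' @param seed Integer seed for the permutation draws.
#' @return An object of class `permutation_result`: list with
#'   `observed_icc_after`, `n_excluded`, `runs`, `n_ge`, `significant`,
#'   `seed` and the vector `permuted_icc`.
#' @export
permutation_icc_test <- function(values, n_excluded, observed_icc_after,
                                 runs = 1000, seed = 1) {
  values <- as.matrix(values)
  n <- nrow(values)
  if (n_excluded < 0) stop("n_excluded must be non-negative")
  if (n - n_excluded < 3)
    stop("too many exclusions: fewer than 3 subjects would remain")
  if (!is.finite(observed_icc_after) || abs(observed_icc_after) > 1)
    stop("invalid observed ICC")
  if (runs < 1) stop("runs must be >= 1")

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  permuted <- vapply(seq_len(runs), function(i) {
    drop_idx <- sample.int(n, n_excluded)
    kept <- if (n_excluded > 0) values[-drop_idx, , drop = FALSE] else values
    suppressWarnings(icc_two_way_random_single(kept)$icc)
  }, numeric(1))
  n_ge <- sum(permuted >= observed_icc_after)
  structure(list(observed_icc_after = observed_icc_after,
                 n_excluded = n_excluded, runs = runs, n_ge = n_ge,
                 significant = n_ge < 0.05 * runs, seed = seed,
                 permuted_icc = permuted),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "Permutation test: observed ICC %.3f, %d/%d permuted ICC >= observed (%s)\n",
    x$observed_icc_after, x$n_ge, x$runs,
    if (x$significant) "significant" else "not significant"))
  invisible(x)
}
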