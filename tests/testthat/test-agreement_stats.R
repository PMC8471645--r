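test_that("DSC follows its definition and symmetry", {
  sp <- c(1, 1, 1)
  a <- array(FALSE, c(6, 6, 6)); a[2:3, 2:3, 2] <- TRUE        # 4 voxels
  b <- array(FALSE, c(6, 6, 6)); b[3:4, 2:3, 2] <- TRUE        # 4, overlap 2
  ma <- binary_mask(a, sp); mb <- binary_mask(b, sp)
  expect_equal(dsc(ma, mb), 0.5)
  expect_equal(dsc(mb, ma), 0.5)
  expect_equal(dsc(ma, ma), 1.0)
  d <- array(FALSE, c(6, 6, 6)); d[5:6, 5:6, 5] <- TRUE
  expect_equal(dsc(ma, binary_mask(d, sp)), 0.0)
  # one-empty is 0, both-empty is an error
  e <- binary_mask(array(FALSE, c(6, 6, 6)), sp)
  expect_equal(dsc(ma, e), 0.0)
  expect_error(dsc(e, e), "empty")
  expect_error(dsc(ma, binary_mask(array(FALSE, c(3, 3, 3)), sp)), "shape")
})

test_that("ICC(2,1) reproduces the hand-worked ANOVA example", {
  r <- icc_two_way_random_single(cbind(c(1, 2, 3), c(2, 3, 4)))
  expect_equal(r$icc, 2 / 3, tolerance = 1e-12)
  expect_true(r$ci_low <= r$icc && r$icc <= r$ci_high)
  # a duplicated column is perfect agreement
  set.seed(9)
  x <- rnorm(10)
  r1 <- icc_two_way_random_single(cbind(x, x))
  expect_equal(r1$icc, 1.0, tolerance = 1e-12)
  # all-identical table: degenerate with warning
  expect_warning(r2 <- icc_two_way_random_single(matrix(3, 5, 2)), "variance")
  expect_equal(c(r2$icc, r2$ci_low, r2$ci_high), c(1, 1, 1))
  # contract violations
  expect_error(icc_two_way_random_single(cbind(1:2, 2:3)), "at least 3")
  expect_error(icc_two_way_random_single(matrix(1:6, 6, 1)), "at least 2")
})

test_that("ICC matches the aov-based oracle on random tables", {
  set.seed(31)
  for (i in 1:200) {
    m <- matrix(rnorm(20, sd = runif(1, 0.5, 3)), 10, 2) +
      rnorm(10, sd = runif(1, 0, 2))
    expect_equal(icc_two_way_random_single(m)$icc, icc_aov_oracle(m),
                 tolerance = 1e-10)
  }
})

test_that("ICC is location and positive-scale invariant", {
  set.seed(12)
  m <- simulate_icc_table(40, 0.7)
  r0 <- icc_two_way_random_single(m)
  r1 <- icc_two_way_random_single(m + 100)
  r2 <- icc_two_way_random_single(m * 7.3)
  expect_equal(r1$icc, r0$icc, tolerance = 1e-10)
  expect_equal(r2$icc, r0$icc, tolerance = 1e-10)
  expect_equal(r1$ci_low, r0$ci_low, tolerance = 1e-8)
  expect_equal(r2$ci_high, r0$ci_high, tolerance = 1e-8)
})

test_that("independent columns give near-zero ICC and missing rows drop", {
  set.seed(77)
  m <- cbind(rnorm(1000), rnorm(1000))
  expect_lt(abs(icc_two_way_random_single(m)$icc), 0.1)
  # complete-case: NA rows are excluded
  m2 <- rbind(simulate_icc_table(30, 0.8), c(NA, 1))
  r <- icc_two_way_random_single(m2)
  expect_equal(r$n_subjects, 30)
})

test_that("CI-overlap significance uses strict disjointness", {
  mk <- function(lo, hi) maskrepro:::new_icc_result((lo + hi) / 2, lo, hi,
                                                    10, 2)
  expect_true(ci_overlap_significant(mk(0.5, 0.7), mk(0.8, 0.9)))
  expect_true(ci_overlap_significant(mk(0.8, 0.9), mk(0.5, 0.7)))
  expect_false(ci_overlap_significant(mk(0.5, 0.85), mk(0.8, 0.9)))
  # touching endpoints count as overlap
  expect_false(ci_overlap_significant(mk(0.5, 0.8), mk(0.8, 0.9)))
})

test_that("Wilcoxon p-values match exact enumeration and known tails", {
  # identical vectors: no signal
  expect_warning(p <- wilcoxon_signed_rank(1:10, 1:10), "zero")
  expect_equal(p, 1)
  # constant positive shift, n = 20: extreme one-sided tail doubled
  x <- rnorm(20)
  expect_lt(wilcoxon_signed_rank(x, x + 1), 0.001)
  # n = 6: exact enumeration over all 2^6 sign assignments
  d <- c(1, -2, 3, -4, 5, 6)
  w_obs <- sum(rank(abs(d))[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), 6)))
  w_all <- signs %*% rank(abs(d))
  p_exact <- mean(abs(w_all - sum(rank(abs(d))) / 2) >=
                    abs(w_obs - sum(rank(abs(d))) / 2))
  expect_equal(wilcoxon_signed_rank(rep(0, 6), d), p_exact,
               tolerance = 1e-12)
  expect_error(wilcoxon_signed_rank(1:3, 2:4), "at least 5")
  expect_error(wilcoxon_signed_rank(1:4, 1:5), "equal length")
})

test_that("Benjamini-Hochberg adjustment is the step-up procedure", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.03), 0.03)
  # hand-computed staircase: sorted q = (0.015, min(.045,.04), .04)
  expect_equal(bh_adjust(c(0.005, 0.04, 0.03)),
               c(0.015, 0.04, 0.04))
  set.seed(3)
  p <- runif(25)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(q <= 1))
  # monotone in rank order
  expect_true(all(diff(q[order(p)]) >= -1e-15))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("Spearman correlation handles monotone maps and ties", {
  x <- c(3, 1, 4, 1.5, 9)
  expect_equal(spearman(x, 2 * x + 1)$rho, 1)
  expect_equal(spearman(x, -x)$rho, -1)
  # hand rank computation: d = (1,1,1,1,0), sum d^2 = 4 on n = 5
  s <- spearman(1:5, c(2, 1, 4, 3, 5))
  expect_equal(s$rho, 1 - 6 * 4 / (5 * 24), tolerance = 1e-12)
  # brute-force rank oracle on a tied sample
  set.seed(2)
  x <- sample(c(1, 2, 2, 3, 5, 8, 8), 7)
  y <- rnorm(7)
  expect_equal(spearman(x, y)$rho, cor(rank(x), rank(y)),
               tolerance = 1e-12)
  expect_warning(s0 <- spearman(rep(1, 5), 1:5), "constant")
  expect_true(is.na(s0$rho))
})

test_that("Bland-Altman bias and limits of agreement are exact", {
  b <- bland_altman(c(10, 20, 30), c(12, 22, 32))
  expect_equal(b$bias, 2)
  expect_equal(b$loa_low, 2)
  expect_equal(b$loa_high, 2)
  b2 <- bland_altman(c(0, 0), c(-1, 1))
  expect_equal(b2$bias, 0)
  expect_equal(b2$loa_high, 1.96 * sqrt(2), tolerance = 1e-12)
  expect_equal(b2$loa_low, -1.96 * sqrt(2), tolerance = 1e-12)
  b3 <- bland_altman(1:10, 1:10)
  expect_equal(c(b3$bias, b3$loa_low, b3$loa_high), c(0, 0, 0))
  expect_error(bland_altman(1:3, 1:4), "equal length")
})

test_that("median percent volume difference summarises paired change", {
  expect_equal(percent_median_difference(c(10, 20), c(10, 20)), 0)
  expect_equal(percent_median_difference(c(10, 20), 0.9 * c(10, 20)), -10)
  expect_equal(percent_median_difference(c(100, 200, 300), c(90, 210, 240)),
               -10)
  expect_error(percent_median_difference(c(0, 1), c(1, 1)), "positive")
})
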