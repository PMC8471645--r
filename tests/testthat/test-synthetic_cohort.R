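# a small, fast configuration used throughout these tests: coarser in-plane
# grid than the study default, which only affects runtime
fast_config <- function(...) {
  args <- list(...)
  if (is.null(args$n_subjects)) args$n_subjects <- 3
  args$spacing <- c(3, 1, 1)
  do.call(synthetic_config, args)
}

test_that("configuration validates its parameters", {
  expect_error(synthetic_config(scan2_compression = 0.4), "compression")
  expect_error(synthetic_config(spurious_component_prob = 1.5), "0, 1")
  expect_error(synthetic_config(method_noise = c(vnet = 1)), "manual")
  expect_error(synthetic_config(method_noise = c(manual = -1, vnet = 1)),
               ">= 0")
})

test_that("zero noise and no deformation give identical paired scans", {
  cfg <- fast_config(method_noise = c(manual = 0, vnet = 1),
                     scan2_compression = 1, scan2_slice_dropout_prob = 0,
                     spurious_component_prob = 0, gross_failure_prob = 0,
                     seed = 21)
  s <- generate_subject(cfg, 1)
  expect_identical(s$label_volumes[["scan1.manual"]]$voxels,
                   s$label_volumes[["scan2.manual"]]$voxels)
  # zero amplitude means the manual mask is the rasterized ground truth:
  # rasterized volume within 3% of the drawn target volume
  wp <- extract_region(s$label_volumes[["scan1.manual"]], "WP")
  expect_lt(abs(voxel_volume(wp) / s$true_params$scan1$target_volume - 1),
            0.03)
})

test_that("generation is bit-reproducible and leaves the RNG untouched", {
  cfg <- fast_config(seed = 33)
  set.seed(555)
  before <- .Random.seed
  s1 <- generate_subject(cfg, 2)
  expect_identical(.Random.seed, before)
  s2 <- generate_subject(cfg, 2)
  for (key in names(s1$label_volumes))
    expect_identical(s1$label_volumes[[key]]$voxels,
                     s2$label_volumes[[key]]$voxels)
  expect_identical(s1$quality_scores, s2$quality_scores)
})

test_that("zone labels partition the gland by construction", {
  cfg <- fast_config(seed = 4)
  s <- generate_subject(cfg, 1)
  for (key in names(s$label_volumes)) {
    lv <- s$label_volumes[[key]]
    pz <- extract_region(lv, "PZ")$voxels
    np <- extract_region(lv, "nonPZ")$voxels
    wp <- extract_region(lv, "WP")$voxels
    expect_false(any(pz & np))
    expect_identical(wp, pz | np)
    expect_gt(sum(pz), 0)
  }
})

test_that("scan-2 compression preserves gland volume but changes shape", {
  cfg <- fast_config(method_noise = c(manual = 0, vnet = 1),
                     scan2_compression = 0.85,
                     scan2_slice_dropout_prob = 0, seed = 10)
  vols1 <- c(); vols2 <- c(); fl1 <- c(); fl2 <- c()
  for (i in 1:3) {
    s <- generate_subject(cfg, i)
    w1 <- extract_region(s$label_volumes[["scan1.manual"]], "WP")
    w2 <- extract_region(s$label_volumes[["scan2.manual"]], "WP")
    vols1 <- c(vols1, voxel_volume(w1)); vols2 <- c(vols2, voxel_volume(w2))
    fl1 <- c(fl1, elongation_flatness(w1)["flatness"])
    fl2 <- c(fl2, elongation_flatness(w2)["flatness"])
    # the analytic semi-axes preserve volume exactly
    p <- s$true_params
    expect_equal(prod(p$scan2$semi_axes), prod(p$scan1$semi_axes),
                 tolerance = 1e-12)
  }
  # rasterized ground-truth volume change stays below 1%
  expect_true(all(abs(vols2 - vols1) / vols1 < 0.01))
  # shape changes: flatness moves notably even though volume does not
  expect_true(all(abs(fl2 - fl1) > 0.01))
})

test_that("a written cohort has complete manifest and stable content", {
  dir1 <- tempfile("cohortA"); dir2 <- tempfile("cohortB")
  on.exit(unlink(c(dir1, dir2), recursive = TRUE))
  cfg <- fast_config(n_subjects = 3,
                     method_noise = c(manual = 0.5, vnet = 1.5), seed = 12)
  out1 <- generate_cohort(cfg, dir1)
  m <- out1$manifest
  # 3 subjects x 2 scans x 2 methods = 12 volumes + manifest
  expect_equal(nrow(m), 12)
  expect_true(all(file.exists(m$path)))
  expect_setequal(names(m), c("subject_id", "scan_id", "method_id", "path",
                              "quality_score"))
  expect_true(all(m$quality_score >= 0 & m$quality_score <= 100))
  # regeneration reproduces identical volumes
  out2 <- generate_cohort(cfg, dir2)
  for (i in seq_len(nrow(m))) {
    a <- read_label_volume(out1$manifest$path[i])
    b <- read_label_volume(out2$manifest$path[i])
    expect_identical(a$voxels, b$voxels)
  }
  expect_identical(out1$manifest$quality_score, out2$manifest$quality_score)
})

test_that("volume reproducibility degrades with boundary noise", {
  amps <- c(0.5, 2, 4)
  iccs <- sapply(amps, function(amp) {
    cfg <- synthetic_config(n_subjects = 14, spacing = c(3, 1, 1),
                            method_noise = c(manual = amp, vnet = 1),
                            scan2_slice_dropout_prob = 0, seed = 77)
    vols <- sapply(1:14, function(i) {
      s <- generate_subject(cfg, i)
      c(voxel_volume(extract_region(s$label_volumes[["scan1.manual"]], "WP")),
        voxel_volume(extract_region(s$label_volumes[["scan2.manual"]], "WP")))
    })
    icc_two_way_random_single(t(vols))$icc
  })
  # non-increasing in noise amplitude (same seed set across amplitudes)
  expect_true(all(diff(iccs) <= 0.02))
  expect_gt(iccs[1], iccs[3])
})

test_that("gross failures depress quality scores below the threshold", {
  cfg <- fast_config(n_subjects = 6, gross_failure_prob = 1,
                     method_noise = c(manual = 0.5, vnet = 1), seed = 19)
  s <- generate_subject(cfg, 1)
  qs <- s$quality_scores
  vnet_scores <- qs$quality_score[qs$method_id == "vnet"]
  manual_scores <- qs$quality_score[qs$method_id == "manual"]
  expect_true(all(vnet_scores < 85))
  expect_true(all(manual_scores > 85))
})
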