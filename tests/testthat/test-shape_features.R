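test_that("voxel volume is count times voxel size", {
  a <- array(FALSE, c(20, 20, 20)); a[1:10, 1:10, 1:10] <- TRUE
  expect_equal(voxel_volume(binary_mask(a, c(3, 0.5, 0.5))), 1000 * 0.75)
  b <- array(FALSE, c(3, 3, 3)); b[2, 2, 2] <- TRUE
  expect_equal(voxel_volume(binary_mask(b, c(1, 1, 1))), 1)
  expect_error(voxel_volume(binary_mask(array(FALSE, c(3, 3, 3)),
                                        c(1, 1, 1))), "empty")
})

test_that("moment features recover uniform-ellipsoid theory", {
  # covariance eigenvalue of a uniform solid ellipsoid is (semi-axis)^2/5
  m <- digitized_ellipsoid(15, 10, 5, 0.5)
  ax <- axis_lengths(m)
  expect_equal(unname(ax["major"]), 4 * 15 / sqrt(5), tolerance = 0.02)
  expect_equal(unname(ax["minor"]), 4 * 10 / sqrt(5), tolerance = 0.02)
  expect_equal(unname(ax["least"]), 4 * 5 / sqrt(5), tolerance = 0.02)
  ef <- elongation_flatness(m)
  expect_equal(unname(ef["elongation"]), 10 / 15, tolerance = 0.02)
  expect_equal(unname(ef["flatness"]), 5 / 15, tolerance = 0.02)
  # ordering invariants
  expect_true(ax["least"] <= ax["minor"] && ax["minor"] <= ax["major"])
  expect_true(ef["flatness"] <= ef["elongation"] &&
                ef["elongation"] <= 1)
})

test_that("degenerate masks have defined moment semantics", {
  # planar mask: least axis and flatness are zero
  a <- array(FALSE, c(7, 9, 9)); a[4, 2:8, 2:8] <- TRUE
  m <- binary_mask(a, c(1, 1, 1))
  expect_equal(unname(axis_lengths(m)["least"]), 0)
  expect_equal(unname(elongation_flatness(m)["flatness"]), 0)
  # single voxel: all lengths zero, ratios undefined with a warning
  b <- array(FALSE, c(5, 5, 5)); b[3, 3, 3] <- TRUE
  sb <- binary_mask(b, c(1, 1, 1))
  expect_equal(unname(axis_lengths(sb)), c(0, 0, 0))
  expect_warning(ef <- elongation_flatness(sb), "degenerate")
  expect_true(all(is.na(ef)))
})

test_that("box diameters follow diagonal geometry", {
  # 30 x 20 x 10 mm extents along (slice, row, column)
  m <- digitized_box(c(30, 20, 10), c(1, 0.5, 0.5))
  d <- max_diameters(m)
  expect_equal(unname(d["d3d"]), sqrt(30^2 + 20^2 + 10^2), tolerance = 0.03)
  expect_equal(unname(d["d_slice"]), sqrt(20^2 + 10^2), tolerance = 0.03)
  expect_equal(unname(d["d_column"]), sqrt(30^2 + 20^2), tolerance = 0.03)
  expect_equal(unname(d["d_row"]), sqrt(30^2 + 10^2), tolerance = 0.03)
})

test_that("the full feature vector is deterministic and complete", {
  m <- digitized_ball(5, 0.5)
  f1 <- extract_features(m)
  f2 <- extract_features(m)
  expect_identical(f1, f2)
  expect_named(f1, feature_names())
  expect_true(all(is.finite(f1)))
  expect_equal(unname(f1["surface_area_to_volume_ratio"]),
               unname(f1["surface_area"] / f1["mesh_volume"]),
               tolerance = 1e-12)
  expect_error(extract_features(binary_mask(array(FALSE, c(3, 3, 3)),
                                            c(1, 1, 1))), "empty")
})

test_that("features are invariant to integer-voxel translation", {
  set.seed(5)
  a <- array(FALSE, c(26, 26, 26))
  a[6:12, 7:14, 6:13] <- TRUE
  a[10:16, 10:15, 9:14] <- TRUE    # lumpy union of two boxes
  m1 <- binary_mask(a, c(1, 0.7, 0.9))
  b <- array(FALSE, c(26, 26, 26))
  b[(6:12) + 7, (7:14) + 4, (6:13) + 9] <- TRUE
  b[(10:16) + 7, (10:15) + 4, (9:14) + 9] <- TRUE
  m2 <- binary_mask(b, c(1, 0.7, 0.9))
  expect_equal(extract_features(m1), extract_features(m2),
               tolerance = 1e-12)
})

test_that("features obey spacing scaling laws", {
  a <- array(FALSE, c(16, 16, 16)); a[4:12, 5:13, 6:12] <- TRUE
  a[8:14, 4:9, 4:9] <- TRUE
  m1 <- binary_mask(a, c(1, 1, 1))
  s <- 2.5
  m2 <- binary_mask(a, c(s, s, s))
  f1 <- extract_features(m1); f2 <- extract_features(m2)
  lengths <- c("least_axis_length", "major_axis_length",
               "minor_axis_length", "max_2d_diameter_column",
               "max_2d_diameter_row", "max_2d_diameter_slice",
               "max_3d_diameter")
  expect_equal(f2[lengths], s * f1[lengths], tolerance = 1e-9)
  expect_equal(unname(f2["mesh_volume"]), s^3 * unname(f1["mesh_volume"]),
               tolerance = 1e-9)
  expect_equal(unname(f2["voxel_volume"]), s^3 * unname(f1["voxel_volume"]),
               tolerance = 1e-9)
  expect_equal(unname(f2["surface_area"]), s^2 * unname(f1["surface_area"]),
               tolerance = 1e-9)
  ratios <- c("elongation", "flatness", "sphericity")
  expect_equal(f2[ratios], f1[ratios], tolerance = 1e-9)
  expect_equal(unname(f2["surface_area_to_volume_ratio"]),
               unname(f1["surface_area_to_volume_ratio"]) / s,
               tolerance = 1e-9)
})

test_that("axis-aligned rotation permutes the 2D diameters consistently", {
  a <- array(FALSE, c(24, 24, 24))
  a[4:18, 6:14, 8:12] <- TRUE
  a[6:10, 8:20, 9:15] <- TRUE
  m <- binary_mask(a, c(1, 1, 1))
  # rotate 90 degrees about the slice axis: swap row and column axes
  mr <- binary_mask(aperm(a, c(1, 3, 2)), c(1, 1, 1))
  f <- extract_features(m); fr <- extract_features(mr)
  inv <- c("elongation", "flatness", "least_axis_length",
           "major_axis_length", "minor_axis_length", "max_3d_diameter",
           "mesh_volume", "voxel_volume", "sphericity", "surface_area",
           "surface_area_to_volume_ratio")
  expect_equal(fr[inv], f[inv], tolerance = 1e-9)
  # in-plane diameter fixed; the other two swap
  expect_equal(unname(fr["max_2d_diameter_slice"]),
               unname(f["max_2d_diameter_slice"]), tolerance = 1e-9)
  expect_equal(unname(fr["max_2d_diameter_row"]),
               unname(f["max_2d_diameter_column"]), tolerance = 1e-9)
  expect_equal(unname(fr["max_2d_diameter_column"]),
               unname(f["max_2d_diameter_row"]), tolerance = 1e-9)
})

test_that("sphericity is definitional and bounded by isoperimetry", {
  v <- 4 / 3 * pi * 10^3; a <- 4 * pi * 10^2
  expect_equal(sphericity(v, a), 1, tolerance = 1e-12)
  expect_error(sphericity(-1, 5), "positive")
  expect_error(sphericity(5, 0), "positive")
  # any non-spherical body: sphericity < 1
  f <- extract_features(digitized_ellipsoid(15, 10, 5, 0.5))
  expect_lt(unname(f["sphericity"]), 1)
})
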