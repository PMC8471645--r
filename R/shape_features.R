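#' Voxel volume of a mask
#'
#' Foreground voxel count times the physical volume of one voxel.
#'
#' @param mask A non-empty [binary_mask()].
#' @return Volume in mm^3.
#' @export
voxel_volume <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  n <- sum(mask$voxels)
  if (n == 0L) stop("empty mask")
  n * prod(mask$spacing)
}

# population (divisor N) covariance eigenvalues of foreground voxel centers
mask_cov_eigenvalues <- function(mask) {
  idx <- which(mask$voxels, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty mask")
  xyz <- sweep(idx, 2, mask$spacing, "*")
  xyz <- sweep(xyz, 2, colMeans(xyz))
  ev <- eigen(crossprod(xyz) / nrow(xyz), symmetric = TRUE,
              only.values = TRUE)$values
  pmax(ev, 0)  # clip numerically tiny negatives
}

#' Principal axis lengths of a mask
#'
#' Lengths `4 * sqrt(lambda_i)` from the eigenvalues
#' `lambda_1 >= lambda_2 >= lambda_3` of the population covariance of the
#' foreground voxel-center coordinates (in mm). For a uniform solid
#' ellipsoid with semi-axis a the corresponding eigenvalue is `a^2/5`, so
#' the major axis length of such a body is `4a/sqrt(5)`. Rank-deficient
#' masks (planar, linear, single voxel) give zero for the corresponding
#' lengths.
#'
#' @param mask A non-empty [binary_mask()].
#' @return Named numeric: `major`, `minor`, `least` (mm).
#' @export
axis_lengths <- function(mask) {
  ev <- mask_cov_eigenvalues(mask)
  setNames(4 * sqrt(ev), c("major", "minor", "least"))
}

#' Elongation and flatness of a mask
#'
#' `elongation = sqrt(lambda_2 / lambda_1)` and
#' `flatness = sqrt(lambda_3 / lambda_1)`, both in (0, 1] with 1 for a
#' sphere-like body. Undefined (with a warning) when the largest eigenvalue
#' is zero, i.e. for a single-voxel mask.
#'
#' @param mask A non-empty [binary_mask()].
#' @return Named numeric: `elongation`, `flatness`; `NA` when undefined.
#' @export
elongation_flatness <- function(mask) {
  ev <- mask_cov_eigenvalues(mask)
  if (ev[1] <= 0) {
    warning("degenerate mask: zero principal eigenvalue, ",
            "elongation/flatness undefined", call. = FALSE)
    return(c(elongation = NA_real_, flatness = NA_real_))
  }
  c(elongation = sqrt(ev[2] / ev[1]), flatness = sqrt(ev[3] / ev[1]))
}

#' Maximum 3D and in-plane 2D diameters
#'
#' Largest pairwise Euclidean distances between mesh vertices: in 3D, and in
#' each of the three image planes (obtained by ignoring one coordinate).
#' Following the usual radiomics convention, the "Slice" diameter ignores
#' the slice coordinate (row-column plane), the "Column" diameter ignores
#' the column coordinate (slice-row plane) and the "Row" diameter ignores
#' the row coordinate (slice-column plane). Distances are exact maxima
#' computed with a grid-pruned all-pairs search.
#'
#' @param mask A non-empty [binary_mask()] (used only when `mesh` is NULL).
#' @param mesh Optional pre-built `triangle_mesh` of `mask`.
#' @return Named numeric: `d3d`, `d_slice`, `d_column`, `d_row` (mm).
#' @export
max_diameters <- function(mask, mesh = NULL) {
  if (is.null(mesh)) mesh <- build_mesh(mask)
  v <- mesh$vertices
  c(d3d = max_pairwise_dist_cpp(v),
    d_slice = planar_diameter(v[, c(2, 3), drop = FALSE]),
    d_column = planar_diameter(v[, c(1, 2), drop = FALSE]),
    d_row = planar_diameter(v[, c(1, 3), drop = FALSE]))
}

# exact 2D diameter: restrict to the convex hull (where the farthest pair
# must lie), then exhaustive search over the few hull points
planar_diameter <- function(p) {
  if (nrow(p) > 500) {
    h <- chull(p[, 1], p[, 2])
    p <- p[h, , drop = FALSE]
  }
  max_pairwise_dist_cpp(p)
}

#' Sphericity of a body
#'
#' `(36 pi V^2)^(1/3) / A`: the ratio of the surface area of a sphere with
#' the body's volume to the body's surface area. Equals 1 for a perfect
#' sphere and is smaller for any other shape (up to small mesh
#' discretization error).
#'
#' @param volume Enclosed volume in mm^3 (> 0).
#' @param area Surface area in mm^2 (> 0).
#' @return Dimensionless ratio.
#' @export
sphericity <- function(volume, area) {
  if (!is.finite(volume) || volume <= 0) stop("volume must be positive")
  if (!is.finite(area) || area <= 0) stop("area must be positive")
  (36 * pi * volume^2)^(1 / 3) / area
}

#' Extract the 14 morphological shape features of a mask
#'
#' Computes, in physical units, the full shape feature vector: elongation,
#' flatness, least/major/minor axis lengths, the three maximum 2D diameters
#' (column, row, slice), maximum 3D diameter, mesh volume, voxel volume,
#' sphericity, surface area, and surface-area-to-volume ratio. Mesh-based
#' quantities use [build_mesh()]; moment-based quantities use the voxel
#' coordinate covariance. Deterministic for a fixed input.
#'
#' @param mask A non-empty [binary_mask()].
#' @param mesh Optional pre-built `triangle_mesh` (saves recomputation).
#' @inheritParams build_mesh
#' @return Named numeric vector of length 14 in the order of
#'   [feature_names()]. Degenerate masks yield `NA` for elongation and
#'   flatness (with a warning); an empty mask is an error.
#' @examples
#' a <- array(FALSE, c(9, 9, 9)); a[3:7, 3:7, 3:7] <- TRUE
#' m <- binary_mask(a, spacing = c(1, 1, 1))
#' extract_features(m)
#' @export
extract_features <- function(mask, mesh = NULL, sigma = 0.7,
                             smooth_iterations = 10) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!any(mask$voxels)) stop("empty mask: no features defined")
  if (is.null(mesh)) mesh <- build_mesh(mask, sigma, smooth_iterations)
  vol <- mesh_volume(mesh)
  area <- surface_area(mesh)
  ax <- axis_lengths(mask)
  ef <- elongation_flatness(mask)
  di <- max_diameters(mask, mesh)
  out <- c(elongation = unname(ef["elongation"]),
           flatness = unname(ef["flatness"]),
           least_axis_length = unname(ax["least"]),
           major_axis_length = unname(ax["major"]),
           minor_axis_length = unname(ax["minor"]),
           max_2d_diameter_column = unname(di["d_column"]),
           max_2d_diameter_row = unname(di["d_row"]),
           max_2d_diameter_slice = unname(di["d_slice"]),
           max_3d_diameter = unname(di["d3d"]),
           mesh_volume = vol,
           voxel_volume = voxel_volume(mask),
           sphericity = sphericity(vol, area),
           surface_area = area,
           surface_area_to_volume_ratio = area / vol)
  out[FEATURE_NAMES]
}
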