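#' Construct a 3D label volume
#'
#' A label volume is a 3D integer grid in slice x row x column order with
#' voxel values 0 (background), 1 (peripheral zone, PZ) and 2 (remaining
#' zones, non-PZ), together with the physical voxel spacing in mm. The whole
#' gland (WP) is the union of the two labelled zones.
#'
#' @param voxels 3D integer array, axes ordered slice x row x column,
#'   values in `{0, 1, 2}`.
#' @param spacing Numeric length-3, voxel size in mm per axis
#'   (slice, row, column); all components must be positive.
#' @param origin Numeric length-3, physical position (mm) of voxel (1,1,1).
#' @param subject_id,scan_id,method_id Identification strings; `scan_id`
#'   must be `"scan1"` or `"scan2"` (or `NA` when not applicable).
#' @return An object of class `label_volume`.
#' @examples
#' a <- array(0L, c(4, 4, 4)); a[2:3, 2:3, 2:3] <- 1L
#' lv <- label_volume(a, spacing = c(3, 0.5, 0.5))
#' @export
label_volume <- function(voxels, spacing, origin = c(0, 0, 0),
                         subject_id = NA_character_, scan_id = NA_character_,
                         method_id = NA_character_) {
  if (length(dim(voxels)) != 3L)
    stop("voxels must be a 3D array")
  if (!is.integer(voxels)) {
    if (any(voxels != round(voxels), na.rm = TRUE))
      stop("invalid label: voxel values must be integers")
    storage.mode(voxels) <- "integer"
  }
  if (anyNA(voxels) || any(voxels < 0L | voxels > 2L))
    stop("invalid label: voxel values must be in {0, 1, 2}")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive numbers (mm)")
  if (!is.na(scan_id) && !scan_id %in% c("scan1", "scan2"))
    stop("scan_id must be 'scan1' or 'scan2'")
  structure(
    list(voxels = voxels, spacing = spacing, origin = as.numeric(origin),
         subject_id = subject_id, scan_id = scan_id, method_id = method_id),
    class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat("label_volume:", paste(dim(x$voxels), collapse = " x "),
      "voxels, spacing", paste(signif(x$spacing, 3), collapse = " x "), "mm\n")
  cat("  subject:", x$subject_id, " scan:", x$scan_id,
      " method:", x$method_id, "\n")
  cat("  foreground: PZ", sum(x$voxels == 1L),
      "voxels, non-PZ", sum(x$voxels == 2L), "voxels\n")
  invisible(x)
}

#' Construct a binary region mask
#'
#' @param voxels 3D logical array (slice x row x column).
#' @param spacing Numeric length-3 voxel size in mm; positive.
#' @param origin Numeric length-3 physical origin in mm.
#' @param region One of `"WP"`, `"PZ"`, `"nonPZ"`.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(voxels, spacing, origin = c(0, 0, 0), region = "WP") {
  if (length(dim(voxels)) != 3L) stop("voxels must be a 3D array")
  if (!is.logical(voxels)) {
    if (!all(voxels %in% c(0, 1))) stop("voxels must be logical or 0/1")
    voxels <- array(as.logical(voxels), dim(voxels))
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive numbers (mm)")
  region <- match.arg(region, REGIONS)
  structure(list(voxels = voxels, spacing = spacing,
                 origin = as.numeric(origin), region = region),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat("binary_mask [", x$region, "]: ",
      paste(dim(x$voxels), collapse = " x "), " voxels, ",
      sum(x$voxels), " foreground (", signif(voxel_volume_raw(x), 4),
      " mm^3)\n", sep = "")
  invisible(x)
}

# foreground volume without the non-empty check (used by print)
voxel_volume_raw <- function(mask) sum(mask$voxels) * prod(mask$spacing)

stop_if_grid_mismatch <- function(a, b) {
  if (!identical(dim(a$voxels), dim(b$voxels)))
    stop("grid shape mismatch between masks")
  if (!isTRUE(all.equal(a$spacing, b$spacing)))
    stop("spacing mismatch between masks")
  invisible(TRUE)
}

#' Read a label volume from a NIfTI file
#'
#' Reads a NIfTI-1 image (`.nii` or `.nii.gz`) containing an integer label
#' map with values in `{0, 1, 2}`. The image is reoriented to a canonical
#' anatomical orientation (RAS) using the header affine, and axes are
#' arranged internally as slice x row x column; voxel spacing is taken from
#' the header `pixdim`.
#'
#' @param path Path to the NIfTI file.
#' @param subject_id,scan_id,method_id Optional identification strings
#'   attached to the returned volume.
#' @return A [label_volume()].
#' @export
read_label_volume <- function(path, subject_id = NA_character_,
                              scan_id = NA_character_,
                              method_id = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) stop("not a 3D image: ", path)
  ornt <- try(RNifti::orientation(img), silent = TRUE)
  if (!inherits(ornt, "try-error") && is.character(ornt) &&
      !is.na(ornt) && nzchar(ornt) && ornt != "RAS") {
    RNifti::orientation(img) <- "RAS"
  }
  px <- RNifti::pixdim(img)
  if (length(px) < 3L || any(px[1:3] <= 0))
    stop("non-positive voxel spacing in NIfTI header: ", path)
  a <- as.array(img)
  if (any(a != round(a))) stop("invalid label: non-integer voxel values")
  storage.mode(a) <- "integer"
  # NIfTI stores (x, y, z) = (column, row, slice); internal order is reversed
  vox <- aperm(a, c(3L, 2L, 1L))
  orig <- attr(img, ".nifti_origin")
  xf <- try(RNifti::xform(img), silent = TRUE)
  origin <- c(0, 0, 0)
  if (!inherits(xf, "try-error") && is.matrix(xf) && all(dim(xf) == c(4, 4)))
    origin <- rev(xf[1:3, 4])
  label_volume(vox, spacing = rev(px[1:3]), origin = origin,
               subject_id = subject_id, scan_id = scan_id,
               method_id = method_id)
}

#' Write a label volume to a NIfTI file
#'
#' Inverse of [read_label_volume()]: voxels, spacing and origin round-trip
#' bit-exactly.
#'
#' @param lv A [label_volume()].
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(lv, path) {
  stopifnot(inherits(lv, "label_volume"))
  a <- aperm(lv$voxels, c(3L, 2L, 1L))
  img <- RNifti::asNifti(a)
  RNifti::pixdim(img) <- rev(lv$spacing)
  if (any(lv$origin != 0)) {
    xf <- structure(diag(c(rev(lv$spacing), 1)), code = 2L)
    xf[1:3, 4] <- rev(lv$origin)
    RNifti::qform(img) <- xf
    RNifti::sform(img) <- xf
  }
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Extract a region mask from a label volume
#'
#' `PZ` selects label 1, `nonPZ` label 2, and `WP` merges both zones
#' (any non-zero label), so that the WP foreground count always equals the
#' sum of the PZ and non-PZ counts.
#'
#' @param lv A [label_volume()].
#' @param region One of `"WP"`, `"PZ"`, `"nonPZ"`.
#' @return A [binary_mask()]; possibly empty (emptiness is an error only in
#'   downstream feature extraction).
#' @export
extract_region <- function(lv, region = c("WP", "PZ", "nonPZ")) {
  stopifnot(inherits(lv, "label_volume"))
  region <- match.arg(region)
  vox <- switch(region,
                WP = lv$voxels > 0L,
                PZ = lv$voxels == 1L,
                nonPZ = lv$voxels == 2L)
  binary_mask(vox, lv$spacing, lv$origin, region)
}

#' Subtract one mask from another
#'
#' Returns the set difference `wp AND NOT pz`; voxels of `pz` lying outside
#' `wp` are ignored. This is how a non-PZ mask is derived from independently
#' produced whole-gland and PZ masks.
#'
#' @param wp,pz [binary_mask()] objects on the same grid.
#' @return A [binary_mask()] with region `"nonPZ"`.
#' @export
subtract_masks <- function(wp, pz) {
  stopifnot(inherits(wp, "binary_mask"), inherits(pz, "binary_mask"))
  stop_if_grid_mismatch(wp, pz)
  binary_mask(wp$voxels & !pz$voxels, wp$spacing, wp$origin, "nonPZ")
}

#' Compose a label volume from separate WP and PZ masks
#'
#' Some segmentation methods predict the whole gland and the peripheral zone
#' independently. This loader reconciles them: PZ voxels outside WP are
#' clipped (dropped), and non-PZ is the set difference WP minus PZ.
#'
#' @param wp,pz [binary_mask()] objects on the same grid.
#' @inheritParams label_volume
#' @return A [label_volume()].
#' @export
compose_label_volume <- function(wp, pz, subject_id = NA_character_,
                                 scan_id = NA_character_,
                                 method_id = NA_character_) {
  stop_if_grid_mismatch(wp, pz)
  pz_in <- wp$voxels & pz$voxels        # clip PZ to WP
  vox <- array(0L, dim(wp$voxels))
  vox[pz_in] <- 1L
  vox[wp$voxels & !pz_in] <- 2L
  label_volume(vox, wp$spacing, wp$origin, subject_id, scan_id, method_id)
}

#' Read a cohort manifest
#'
#' The manifest is a CSV with columns `subject_id`, `scan_id`, `method_id`,
#' `path` and optionally `quality_score`, one row per volume.
#'
#' @param path Path to the manifest CSV.
#' @return A data frame.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  m <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "scan_id", "method_id", "path")
  miss <- setdiff(need, names(m))
  if (length(miss))
    stop("manifest missing columns: ", paste(miss, collapse = ", "))
  if (!all(m$scan_id %in% c("scan1", "scan2")))
    stop("manifest scan_id values must be 'scan1' or 'scan2'")
  m
}
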