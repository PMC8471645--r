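#' Label the connected components of a mask
#'
#' @param mask A [binary_mask()].
#' @param connectivity 6 (faces), 18 (faces + edges) or 26 (faces + edges +
#'   corners).
#' @return Integer 3D array of component labels (0 = background) with an
#'   attribute `n_components`.
#' @export
connected_components <- function(mask, connectivity = 26) {
  stopifnot(inherits(mask, "binary_mask"))
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26")
  label_components_cpp(mask$voxels, connectivity)
}

#' Keep only the largest 3D connected component
#'
#' Segmentation post-processing step: all foreground components except the
#' one with the largest voxel count are removed. A tie between equal-sized
#' components is broken deterministically by keeping the component that
#' contains the lexicographically smallest (slice, row, column) voxel index.
#'
#' @inheritParams connected_components
#' @return A [binary_mask()] whose foreground is a single connected
#'   component; a subset of the input, and idempotent.
#' @export
largest_component <- function(mask, connectivity = 26) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!any(mask$voxels)) stop("empty mask: no foreground voxels")
  lab <- connected_components(mask, connectivity)
  ncomp <- attr(lab, "n_components")
  if (ncomp == 1L) return(mask)
  sizes <- tabulate(lab[lab > 0L], nbins = ncomp)
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # tie-break: component containing the smallest (slice,row,col) voxel
    key <- vapply(best, function(k) {
      idx <- which(lab == k, arr.ind = TRUE)
      ord <- order(idx[, 1L], idx[, 2L], idx[, 3L])
      paste(sprintf("%06d", idx[ord[1L], ]), collapse = "")
    }, character(1))
    best <- best[which.min(key)]
  }
  binary_mask(array(lab == best, dim(mask$voxels)), mask$spacing,
              mask$origin, mask$region)
}

#' Post-process a label volume
#'
#' Applies [largest_component()] independently to each zone mask (PZ and
#' non-PZ) and recomposes the label volume; the whole-gland mask is then
#' implicitly re-derived by merging the cleaned zones. A zone that is empty
#' (before or after cleaning) produces a warning, not an error.
#'
#' @param lv A [label_volume()].
#' @param connectivity Passed to [largest_component()]; default 26.
#' @return A post-processed [label_volume()].
#' @export
postprocess_label_volume <- function(lv, connectivity = 26) {
  stopifnot(inherits(lv, "label_volume"))
  out <- array(0L, dim(lv$voxels))
  for (region in c("PZ", "nonPZ")) {
    m <- extract_region(lv, region)
    if (!any(m$voxels)) {
      warning("region ", region, " is empty in subject ",
              lv$subject_id, call. = FALSE)
      next
    }
    cleaned <- largest_component(m, connectivity)
    lab <- if (region == "PZ") 1L else 2L
    if (any(out[cleaned$voxels] != 0L))
      stop("internal error: cleaned regions overlap")
    out[cleaned$voxels] <- lab
  }
  label_volume(out, lv$spacing, lv$origin, lv$subject_id, lv$scan_id,
               lv$method_id)
}
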