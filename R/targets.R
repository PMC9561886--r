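# Training targets: Gaussian heatmaps with a false-positive suppression band,
# one-hot segmentation targets and straddle-slice labels.

#' Gaussian heatmap target with false-positive suppression band
#'
#' Builds the per-voxel regression target for landmark localization: a 3D
#' Gaussian centred at the landmark, rescaled so the voxel containing the
#' landmark is exactly 1. Voxels whose centres lie within `support_radius` mm
#' of the landmark carry the Gaussian value; the shell between
#' `support_radius` and `support_radius + suppression_band` is flagged invalid
#' and must be excluded from any loss (this is the false-positive suppression
#' band: near-landmark voxels are neither positive targets nor trusted
#' negatives); everything farther is background 0.
#'
#' @param geom the [geometry()] of the target grid.
#' @param landmark physical mm 3-vector, inside the grid.
#' @param sigma Gaussian sd in mm (> 0). Default 3 mm, comparable to slice
#'   thickness and well inside a 12 mm class third.
#' @param support_radius truncation radius in mm (>= sigma); default 3 sigma.
#' @param suppression_band width in mm of the invalid shell outside the
#'   support; default 2 mm.
#' @param grid_shape integer 3-vector of the target grid shape.
#' @return object of class `acl_heatmap_target`: `values` (3D array in
#'   \[0, 1\]), `invalid_mask` (3D logical), `landmark_index` (fractional
#'   voxel 3-vector).
#' @export
gaussian_heatmap <- function(geom, landmark, grid_shape, sigma = 3,
                             support_radius = 3 * sigma,
                             suppression_band = 2) {
  stopifnot(sigma > 0, support_radius >= sigma, suppression_band >= 0)
  n <- as.integer(grid_shape)
  li <- physical_to_voxel(geom, landmark)
  if (any(li < -0.5) || any(li > n - 0.5)) stop("landmark outside grid")
  idx <- as.matrix(expand.grid(x = 0:(n[1] - 1), y = 0:(n[2] - 1),
                               z = 0:(n[3] - 1)))
  p <- voxel_to_physical(geom, idx)
  d2 <- rowSums(sweep(p, 2, as.numeric(landmark))^2)
  vals <- exp(-d2 / (2 * sigma^2))
  inside <- d2 <= support_radius^2
  vals[!inside] <- 0
  # rescale so the voxel containing the landmark (nearest centre) is exactly 1
  vals[inside] <- vals[inside] / max(vals[inside])
  invalid <- !inside & d2 <= (support_radius + suppression_band)^2
  structure(list(values = array(vals, n),
                 invalid_mask = array(invalid, n),
                 landmark_index = li,
                 geometry = geom),
            class = "acl_heatmap_target")
}

#' One-hot segmentation target from a label map
#'
#' @param labels an [label_map()].
#' @return 4D array (class, x, y, z) with exactly one class active per voxel;
#'   class count equals `length(labels$label_names)`.
#' @export
seg_target <- function(labels) {
  stopifnot(inherits(labels, "acl_labelmap"))
  k <- length(labels$label_names)
  d <- dim(labels$data)
  out <- array(0, c(k, d))
  flat <- as.integer(labels$data)
  out[cbind(flat + 1L, as.matrix(expand.grid(1:d[1], 1:d[2], 1:d[3])))] <- 1
  out
}

#' Straddle-slice target for the 2D slice-selection network
#'
#' The landmark's slice-axis voxel coordinate is generally fractional; the two
#' integer slices straddling it are supervised with weights split linearly by
#' the fractional part (weight `1 - frac` on `floor(z)`, `frac` on `ceil(z)`),
#' preserving sub-slice information under a cross-entropy loss.
#'
#' @param geom the [geometry()] of the (cropped, resampled) slab.
#' @param landmark physical mm 3-vector.
#' @param n_slices number of slices in the slab.
#' @return object of class `acl_slice_target`: `straddle` (pair of 0-based
#'   slice indices differing by at most 1) and `target_vector` (length
#'   `n_slices`, non-negative, sums to 1).
#' @export
slice_target <- function(geom, landmark, n_slices) {
  z <- physical_to_voxel(geom, landmark)[3]
  if (z < 0 || z > n_slices - 1) stop("landmark outside the slice range")
  z0 <- floor(z); z1 <- ceiling(z)
  frac <- z - z0
  tv <- numeric(n_slices)
  tv[z0 + 1] <- tv[z0 + 1] + (1 - frac)
  tv[z1 + 1] <- tv[z1 + 1] + frac
  structure(list(straddle = c(z0, z1), target_vector = tv),
            class = "acl_slice_target")
}

#' Bounding-box target for the keypoint detector
#'
#' The keypoint is represented as the centre of a fixed-size box (the detector
#' predicts the box and the keypoint is read off as its centre).
#'
#' @param center in-plane pixel pair (0-based, fractional allowed).
#' @param size in-plane box size in pixels (> 0).
#' @param image_shape in-plane grid shape, for the bounds check.
#' @return list with `center` and `size`.
#' @export
box_target <- function(center, size, image_shape) {
  center <- as.numeric(center); size <- as.numeric(size)
  stopifnot(length(center) == 2, all(size > 0))
  if (any(center < 0) || any(center > image_shape - 1))
    stop("box centre outside image bounds")
  list(center = center, size = size)
}
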