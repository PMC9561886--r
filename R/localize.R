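# From trained (or oracle) models to physical rupture coordinates: ROI
# extraction from segmentation, 3D heatmap decoding, 2D slice + box decoding.

#' Localization configuration
#'
#' @param margin_mm padding added around the footprint/ACL extent when cropping
#'   the ROI.
#' @param patch_shape fixed voxel shape of the 3D patch cropped from the
#'   source grid before resampling.
#' @param patch_spacing in-plane mm spacing the 3D patch is resampled to
#'   before entering the heatmap net; the resulting grid must be divisible by
#'   `2^(depth-1)` of the net. The defaults (48x48x16 crop at 1 mm, resampled
#'   to 1.5 mm) give a 32x32x16 input covering a 48x48x48 mm field of view.
#' @param threshold heatmap probability threshold for centroid decoding.
#' @param centroid `"weighted"` (probability-weighted, sub-voxel stable) or
#'   `"binary"` (unweighted centroid of the thresholded region).
#' @param inplane_mm in-plane resampling target for the 2D route (mm).
#' @param inplane_px in-plane image size fed to the 2D nets (power of two).
#' @param n_slices slab thickness (slices) for the slice-selection net.
#' @return list of class `acl_localize_config`.
#' @export
localize_config <- function(margin_mm = 6, patch_shape = c(48, 48, 16),
                            patch_spacing = c(1.5, 1.5),
                            threshold = 0.5,
                            centroid = c("weighted", "binary"),
                            inplane_mm = 0.25, inplane_px = 256,
                            n_slices = 6) {
  structure(list(margin_mm = margin_mm, patch_shape = as.integer(patch_shape),
                 patch_spacing = as.numeric(patch_spacing),
                 threshold = threshold, centroid = match.arg(centroid),
                 inplane_mm = inplane_mm, inplane_px = inplane_px,
                 n_slices = n_slices),
            class = "acl_localize_config")
}

.as_label_array <- function(seg) {
  if (inherits(seg, "acl_labelmap")) return(seg$data)
  if (length(dim(seg)) == 4) {
    d <- dim(seg)
    flat <- matrix(seg, d[1])
    return(array(max.col(t(flat), ties.method = "first") - 1L, d[2:4]))
  }
  seg
}

#' Derive the ACL region of interest from a segmentation
#'
#' The ROI box is the bounding box of all foreground classes (both footprints
#' and ACL tissue) dilated by `margin_mm` and clipped to the grid; the
#' footprint centroids are the per-class voxel centroids mapped to physical mm.
#' An empty footprint class signals a segmentation failure and is an error
#' (callers record the case and abort its pipeline).
#'
#' @param seg per-voxel class scores `(C, X, Y, Z)`, a label array, or an
#'   [label_map()].
#' @param geom the volume's [geometry()].
#' @param margin_mm dilation margin in mm.
#' @return list of class `acl_roi`: `box` (inclusive voxel bounds), and
#'   `femoral_center`, `tibial_center`, `center` in physical mm.
#' @export
roi_from_segmentation <- function(seg, geom, margin_mm = 6) {
  lab <- .as_label_array(seg)
  d <- dim(lab)
  centroid_of <- function(cls) {
    idx <- which(lab == cls)
    if (length(idx) == 0)
      stop("segmentation failure: footprint class ", cls, " is empty")
    v <- arrayInd(idx, d) - 1
    voxel_to_physical(geom, colMeans(v))
  }
  fem <- centroid_of(1L)
  tib <- centroid_of(2L)
  fg <- which(lab > 0L)
  vi <- arrayInd(fg, d) - 1
  mvox <- ceiling(margin_mm / geom$spacing)
  lo <- pmax(apply(vi, 2, min) - mvox, 0)
  hi <- pmin(apply(vi, 2, max) + mvox, d - 1)
  box <- list(min = as.integer(lo), max = as.integer(hi))
  center <- voxel_to_physical(geom, (lo + hi) / 2)
  structure(list(box = box, femoral_center = fem, tibial_center = tib,
                 center = center, margin_mm = margin_mm), class = "acl_roi")
}

#' ROI directly from a ground-truth label map
#'
#' Oracle-segmentation convenience: identical to [roi_from_segmentation()] on
#' the one-hot encoding of the labels.
#'
#' @param labels an [label_map()].
#' @param margin_mm dilation margin in mm.
#' @export
roi_from_labels <- function(labels, margin_mm = 6) {
  roi_from_segmentation(labels$data, labels$geometry, margin_mm)
}

.localization_result <- function(point, method, fallback_used = FALSE,
                                 low_confidence = FALSE) {
  structure(list(point = as.numeric(point), method = method,
                 fallback_used = fallback_used,
                 low_confidence = low_confidence),
            class = "acl_localization")
}

#' Decode a probability heatmap into a physical coordinate
#'
#' Thresholds the heatmap at `threshold` and returns the centroid of the
#' suprathreshold region in physical mm (probability-weighted by default;
#' `centroid = "binary"` for the unweighted centroid). If no voxel reaches the
#' threshold, the decoder falls back to the global maximum (first in scan
#' order on ties) and flags `fallback_used` so failure statistics stay honest.
#'
#' @param prob 3D array of probabilities in \[0, 1\] (a leading singleton
#'   channel dimension is accepted).
#' @param geom the grid's [geometry()].
#' @param threshold probability threshold (default 0.5).
#' @param centroid `"weighted"` or `"binary"`.
#' @return an `acl_localization` (fields `point`, `method`, `fallback_used`).
#' @export
decode_heatmap <- function(prob, geom, threshold = 0.5,
                           centroid = c("weighted", "binary")) {
  centroid <- match.arg(centroid)
  if (length(dim(prob)) == 4) prob <- array(prob[1, , , ], dim(prob)[2:4])
  stopifnot(min(prob) >= 0, max(prob) <= 1)
  d <- dim(prob)
  sel <- which(prob >= threshold)
  if (length(sel) == 0) {
    v <- arrayInd(which.max(prob), d) - 1
    return(.localization_result(voxel_to_physical(geom, drop(v)), "heatmap3d",
                                fallback_used = TRUE))
  }
  vi <- arrayInd(sel, d) - 1
  w <- if (centroid == "weighted") prob[sel] else rep(1, length(sel))
  cen <- colSums(vi * w) / sum(w)
  .localization_result(voxel_to_physical(geom, cen), "heatmap3d")
}

#' Decode slice scores plus a box centre into a physical coordinate
#'
#' The argmax slice (lowest index on ties, flagged low-confidence when tied)
#' supplies the slice coordinate; the in-plane coordinates come from the
#' predicted box centre. The slab geometry already encodes any cropping and
#' resampling, so the result is in scanner physical mm.
#'
#' @param slice_scores probability vector over the slab's slices.
#' @param box_center in-plane pixel pair (0-based) in the slab's grid.
#' @param roi_geometry [geometry()] of the (cropped, resampled) slab.
#' @return an `acl_localization` with `method = "slice2d"`.
#' @export
decode_2d <- function(slice_scores, box_center, roi_geometry) {
  z <- which.max(slice_scores) - 1
  low <- sum(slice_scores == max(slice_scores)) > 1
  pt <- voxel_to_physical(roi_geometry, c(box_center[1], box_center[2], z))
  .localization_result(pt, "slice2d", low_confidence = low)
}

# shared patch pipeline: fixed-shape crop around the ROI centre, then
# in-plane resampling to the configured spacing (training and inference use
# this identical path)
.loc_patch <- function(vol, center_mm, config) {
  patch <- crop_centered(vol, center_mm, config$patch_shape)
  if (max(abs(patch$geometry$spacing[1:2] - config$patch_spacing)) > 1e-9)
    patch <- resample_in_plane(patch, config$patch_spacing)
  patch
}

# z-score a patch; constant patches pass through unscaled
.normalize_patch <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) s <- 1
  (x - mean(x)) / s
}

.run_model <- function(model, x) {
  if (is.function(model)) model(x) else {
    xx <- x
    if (length(dim(xx)) == 3) dim(xx) <- c(1, dim(xx))
    net_forward(model, xx)
  }
}

# pad (with zeros) or crop a volume to an exact in-plane shape, centred
.fit_inplane <- function(vol, px) {
  d <- dim(vol$data)
  out <- array(0, c(px, px, d[3]))
  src_lo <- pmax((d[1:2] - px) %/% 2, 0)
  dst_lo <- pmax((px - d[1:2]) %/% 2, 0)
  n <- pmin(d[1:2], px)
  out[dst_lo[1] + 1:n[1], dst_lo[2] + 1:n[2], ] <-
    vol$data[src_lo[1] + 1:n[1], src_lo[2] + 1:n[2], , drop = FALSE]
  g <- vol$geometry
  origin <- voxel_to_physical(g, c(src_lo - dst_lo, 0))
  volume(out, geometry(g$spacing, origin, g$orientation))
}

#' Localize the rupture point in one volume, end to end
#'
#' Runs the cascade: segmentation, ROI extraction, patch cropping (plus
#' in-plane resampling for the 2D route), localization model, decoding. The
#' result is in the original scanner physical coordinates. Models may be
#' trained networks or oracle functions (taking the normalized input array and
#' returning the network-shaped output), which is how the decoding and
#' classification stages are validated independently of training.
#'
#' @param vol an [volume()].
#' @param seg_model segmentation net, or a function of the `(1, X, Y, Z)`
#'   input array returning class scores, or an [label_map()] used directly.
#' @param loc_model for `mode = "heatmap3d"`: heatmap net or function of the
#'   patch array; for `mode = "slice2d"`: a list with elements `slice` and
#'   `det` (each a net or function).
#' @param mode `"heatmap3d"` or `"slice2d"`.
#' @param config a [localize_config()].
#' @return an `acl_localization`, with the ROI attached as attribute `roi`.
#' @export
localize_case <- function(vol, seg_model, loc_model,
                          mode = c("heatmap3d", "slice2d"),
                          config = localize_config()) {
  mode <- match.arg(mode)
  roi <- if (inherits(seg_model, "acl_labelmap")) {
    roi_from_labels(seg_model, config$margin_mm)
  } else {
    xin <- .normalize_patch(vol$data)
    dim(xin) <- c(1, dim(vol$data))
    seg <- if (is.function(seg_model)) seg_model(xin)
           else net_forward(seg_model, xin)
    roi_from_segmentation(seg, vol$geometry, config$margin_mm)
  }
  if (mode == "heatmap3d") {
    patch <- .loc_patch(vol, roi$center, config)
    x <- .normalize_patch(patch$data)
    prob <- .run_model(loc_model, x)
    res <- decode_heatmap(prob, patch$geometry, config$threshold,
                          config$centroid)
  } else {
    d <- dim(vol$data)
    zc <- round(physical_to_voxel(vol$geometry, roi$center))[3]
    z0 <- min(max(zc - config$n_slices %/% 2, 0), max(d[3] - config$n_slices, 0))
    z1 <- min(z0 + config$n_slices - 1, d[3] - 1)
    slab <- crop_patch(vol, list(min = c(roi$box$min[1:2], z0),
                                 max = c(roi$box$max[1:2], z1)))
    slab <- resample_in_plane(slab, rep(config$inplane_mm, 2))
    slab <- .fit_inplane(slab, config$inplane_px)
    xs <- .normalize_patch(slab$data)
    scores <- .run_model(loc_model$slice, xs)
    z <- which.max(scores) - 1
    sl <- xs[, , z + 1]
    dim(sl) <- c(dim(sl), 1)
    det_out <- .run_model(loc_model$det, sl)
    bc <- if (is.list(det_out)) det_out$center
          else decode_detection(det_out, loc_model$det)$center
    res <- decode_2d(scores, bc, slab$geometry)
  }
  attr(res, "roi") <- roi
  res
}

#' Write a QC overlay of predicted vs true rupture points
#'
#' Renders the slab slice through the predicted point with the prediction
#' marked in red and the truth in green (cross markers), as a PNG.
#'
#' @param vol an [volume()].
#' @param pred,truth physical mm 3-vectors.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
qc_overlay <- function(vol, pred, truth, path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required for QC overlays")
  d <- dim(vol$data)
  zp <- min(max(round(physical_to_voxel(vol$geometry, pred))[3], 0), d[3] - 1)
  sl <- vol$data[, , zp + 1]
  rng <- range(sl)
  gray <- if (diff(rng) > 0) (sl - rng[1]) / diff(rng) else sl * 0
  img <- array(rep(gray, 3), c(d[1], d[2], 3))
  mark <- function(img, p, ch) {
    v <- round(physical_to_voxel(vol$geometry, p))[1:2]
    v <- pmin(pmax(v, 0), d[1:2] - 1)
    for (o in -2:2) {
      xi <- min(max(v[1] + o, 0), d[1] - 1) + 1
      yi <- min(max(v[2] + o, 0), d[2] - 1) + 1
      img[xi, v[2] + 1, ] <- 0; img[xi, v[2] + 1, ch] <- 1
      img[v[1] + 1, yi, ] <- 0; img[v[1] + 1, yi, ch] <- 1
    }
    img
  }
  img <- mark(img, pred, 1)
  img <- mark(img, truth, 2)
  png::writePNG(aperm(img, c(2, 1, 3)), path)
  invisible(path)
}
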