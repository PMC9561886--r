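#' 3D intensity volume with physical geometry
#'
#' @param data 3D numeric array of intensities (all finite).
#' @param geom a [geometry()].
#' @return an object of class `acl_volume`.
#' @export
volume <- function(data, geom) {
  stopifnot(inherits(geom, "acl_geometry"))
  data <- as.array(data)
  if (length(dim(data)) != 3 || any(dim(data) < 1))
    stop("data must be a 3D array with every dimension >= 1")
  if (!all(is.finite(data))) stop("intensities must be finite")
  structure(list(data = data, geometry = geom), class = "acl_volume")
}

#' @export
print.acl_volume <- function(x, ...) {
  cat("<volume>", paste(dim(x$data), collapse = "x"), "voxels, spacing",
      paste(signif(x$geometry$spacing, 4), collapse = "x"), "mm\n")
  invisible(x)
}

#' Integer label map paired with a volume grid
#'
#' Labels follow the ITK-SNAP convention: contiguous non-negative integers with
#' 0 = background. `label_names` names every label present.
#'
#' @param data 3D array of non-negative integer labels.
#' @param geom a [geometry()].
#' @param label_names character vector naming labels `0..K-1` (first entry is
#'   the background).
#' @return an object of class `acl_labelmap`.
#' @export
label_map <- function(data, geom,
                      label_names = c("background", "femoral_footprint",
                                      "tibial_footprint", "acl")) {
  stopifnot(inherits(geom, "acl_geometry"))
  data <- as.array(data)
  if (length(dim(data)) != 3) stop("data must be a 3D array")
  u <- sort(unique(as.integer(data)))
  if (any(u < 0)) stop("labels must be non-negative")
  if (max(u) >= length(label_names))
    stop("label value without a name: ", max(u))
  storage.mode(data) <- "integer"
  structure(list(data = data, geometry = geom, label_names = label_names),
            class = "acl_labelmap")
}

# LPS <-> RAS: NIfTI affines address RAS+; flip the sign of the first two
# physical axes to get the internal LPS frame.
.ras_to_lps <- function(aff) {
  aff[1:2, ] <- -aff[1:2, ]
  aff
}

.geometry_from_affine <- function(aff) {
  m <- aff[1:3, 1:3]
  spacing <- sqrt(colSums(m^2))
  geometry(spacing = spacing, origin = aff[1:3, 4],
           orientation = sweep(m, 2, spacing, `/`))
}

#' Read a volume from NIfTI or a DICOM series directory
#'
#' NIfTI files (`.nii`/`.nii.gz`) are read through RNifti and their RAS affine
#' converted to the internal LPS frame. A directory is treated as one DICOM
#' series: slices are sorted by position projected on the slice normal (never
#' by filename), a mixed-series directory is an error, and non-uniform slice
#' spacing beyond 1e-3 mm signals a corrupt series.
#'
#' @param path a NIfTI file or a directory containing a single DICOM series.
#' @return an [volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file or directory: ", path)
  if (dir.exists(path)) return(read_dicom_series(path))
  img <- RNifti::readNifti(path)
  aff <- .ras_to_lps(structure(RNifti::xform(img), code = NULL))
  dat <- as.array(img)
  if (length(dim(dat)) != 3) stop("expected a 3D NIfTI volume")
  volume(array(as.numeric(dat), dim(dat)), .geometry_from_affine(aff))
}

#' Read a label map from NIfTI
#'
#' @inheritParams read_volume
#' @param label_names names for labels `0..K-1`.
#' @return an [label_map()].
#' @export
read_label_map <- function(path, label_names = c("background",
                                                 "femoral_footprint",
                                                 "tibial_footprint", "acl")) {
  v <- read_volume(path)
  label_map(round(v$data), v$geometry, label_names)
}

#' Write a volume (or label map) to NIfTI
#'
#' The internal LPS geometry is converted back to a RAS sform so the file
#' round-trips through any NIfTI-aware viewer (ITK-SNAP included).
#'
#' @param vol an [volume()] or [label_map()].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  dat <- vol$data
  if (inherits(vol, "acl_labelmap")) storage.mode(dat) <- "integer"
  aff_ras <- .ras_to_lps(geometry_affine(vol$geometry))  # involution
  img <- RNifti::asNifti(dat)
  img <- RNifti::`sform<-`(img, structure(aff_ras, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Crop a voxel-aligned patch, preserving physical coordinates
#'
#' The cropped volume's origin is updated so every retained voxel maps to the
#' same physical point as before (landmark coordinates are crop-invariant).
#'
#' @param vol an [volume()] or [label_map()].
#' @param box list with integer vectors `min` and `max`: inclusive 0-based
#'   voxel bounds per axis.
#' @return the cropped object, same class as `vol`.
#' @export
crop_patch <- function(vol, box) {
  d <- dim(vol$data)
  lo <- as.integer(box$min); hi <- as.integer(box$max)
  if (any(lo < 0) || any(hi > d - 1L) || any(lo > hi))
    stop("crop box out of bounds")
  dat <- vol$data[(lo[1] + 1):(hi[1] + 1), (lo[2] + 1):(hi[2] + 1),
                  (lo[3] + 1):(hi[3] + 1), drop = FALSE]
  g <- vol$geometry
  ng <- geometry(g$spacing, voxel_to_physical(g, lo), g$orientation)
  if (inherits(vol, "acl_labelmap")) label_map(dat, ng, vol$label_names)
  else volume(dat, ng)
}

# Bilinear sample of one 2D slice at fractional 0-based coords (matrices xq,
# yq); values outside the grid clamp to the edge.
.bilinear_slice <- function(sl, xq, yq) {
  nx <- nrow(sl); ny <- ncol(sl)
  xq <- pmin(pmax(xq, 0), nx - 1); yq <- pmin(pmax(yq, 0), ny - 1)
  x0 <- pmin(floor(xq), nx - 2); y0 <- pmin(floor(yq), ny - 2)
  fx <- xq - x0; fy <- yq - y0
  i00 <- cbind(as.vector(x0) + 1, as.vector(y0) + 1)
  v00 <- sl[i00]; v10 <- sl[i00 + rep(c(1L, 0L), each = nrow(i00))]
  v01 <- sl[i00 + rep(c(0L, 1L), each = nrow(i00))]
  v11 <- sl[i00 + 1L]
  fx <- as.vector(fx); fy <- as.vector(fy)
  v00 * (1 - fx) * (1 - fy) + v10 * fx * (1 - fy) +
    v01 * (1 - fx) * fy + v11 * fx * fy
}

#' Resample a volume in-plane to a target spacing
#'
#' Slice count and slice spacing are unchanged; each slice is resampled on a
#' grid with the requested in-plane spacing covering the same physical extent.
#' Intensities are interpolated linearly, labels by nearest neighbour.
#'
#' @param vol an [volume()] or [label_map()].
#' @param target_spacing length-2 positive mm pair for the in-plane axes.
#' @return the resampled object, same class as `vol`.
#' @export
resample_in_plane <- function(vol, target_spacing) {
  ts <- as.numeric(target_spacing)
  stopifnot(length(ts) == 2)
  if (any(!is.finite(ts)) || any(ts <= 0)) stop("target spacing must be > 0")
  g <- vol$geometry
  d <- dim(vol$data)
  is_label <- inherits(vol, "acl_labelmap")
  # new in-plane grid covering the old physical extent (voxel-centre aligned)
  nx <- max(2L, as.integer(round((d[1] - 1) * g$spacing[1] / ts[1])) + 1L)
  ny <- max(2L, as.integer(round((d[2] - 1) * g$spacing[2] / ts[2])) + 1L)
  xq <- (seq_len(nx) - 1) * ts[1] / g$spacing[1]
  yq <- (seq_len(ny) - 1) * ts[2] / g$spacing[2]
  XQ <- matrix(xq, nx, ny); YQ <- matrix(yq, nx, ny, byrow = TRUE)
  if (is_label) { XQ <- round(XQ); YQ <- round(YQ) }
  out <- array(0, c(nx, ny, d[3]))
  for (k in seq_len(d[3]))
    out[, , k] <- matrix(.bilinear_slice(vol$data[, , k], XQ, YQ), nx, ny)
  ng <- geometry(c(ts, g$spacing[3]), g$origin, g$orientation)
  if (is_label) label_map(round(out), ng, vol$label_names)
  else volume(out, ng)
}

#' Crop a fixed-shape patch centred on a physical point
#'
#' Convenience for feeding fixed-size network inputs: the patch is `shape`
#' voxels, centred as close to `center_mm` as the grid allows (shifted, never
#' padded, when the centre is near a border). Requires `shape <= dim(vol)`.
#'
#' @param vol an [volume()] or [label_map()].
#' @param center_mm physical mm point the patch should centre on.
#' @param shape integer length-3 patch shape in voxels.
#' @return cropped object, same class as `vol`.
#' @export
crop_centered <- function(vol, center_mm, shape) {
  d <- dim(vol$data)
  shape <- as.integer(shape)
  if (any(shape > d)) stop("patch shape exceeds grid")
  cv <- round(physical_to_voxel(vol$geometry, center_mm))
  lo <- pmin(pmax(cv - shape %/% 2L, 0L), d - shape)
  crop_patch(vol, list(min = lo, max = lo + shape - 1L))
}
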