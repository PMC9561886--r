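#' Image geometry: voxel to physical coordinate mapping
#'
#' A `geometry` ties a voxel grid to the scanner's physical space. All physical
#' coordinates in this package are millimetres in the LPS frame (the DICOM
#' convention: +x left, +y posterior, +z superior); NIfTI RAS headers are
#' converted on read. Voxel indices are 0-based and may be fractional, so
#' sub-voxel landmarks (centroids, Gaussian centres) live in the same algebra
#' as grid points.
#'
#' @param spacing numeric length-3, mm per voxel step along each axis; all > 0.
#' @param origin numeric length-3, physical mm coordinate of voxel (0,0,0).
#' @param orientation 3x3 direction matrix with orthonormal columns: column j
#'   is the physical direction of voxel axis j.
#' @return an object of class `acl_geometry`.
#' @examples
#' g <- geometry(spacing = c(0.5, 0.5, 3))
#' voxel_to_physical(g, c(4, 4, 1))
#' @export
geometry <- function(spacing, origin = c(0, 0, 0), orientation = diag(3)) {
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  orientation <- matrix(as.numeric(orientation), 3, 3)
  stopifnot(length(spacing) == 3, length(origin) == 3)
  if (!all(is.finite(spacing)) || any(spacing <= 0))
    stop("spacing components must be finite and > 0")
  if (!all(is.finite(origin))) stop("origin must be finite")
  if (max(abs(crossprod(orientation) - diag(3))) > 1e-6)
    stop("orientation must be orthonormal")
  if (abs(abs(det(orientation)) - 1) > 1e-6)
    stop("orientation must have |det| = 1")
  structure(list(spacing = spacing, origin = origin, orientation = orientation),
            class = "acl_geometry")
}

#' @export
print.acl_geometry <- function(x, ...) {
  cat("<geometry> spacing", paste(signif(x$spacing, 4), collapse = "x"),
      "mm, origin (", paste(signif(x$origin, 4), collapse = ", "), ") mm\n")
  invisible(x)
}

#' 4x4 voxel-to-physical affine of a geometry
#'
#' Maps homogeneous 0-based voxel indices to physical mm:
#' `p = origin + orientation %*% (spacing * index)`.
#'
#' @param geom a [geometry()].
#' @return 4x4 numeric matrix.
#' @export
geometry_affine <- function(geom) {
  a <- diag(4)
  a[1:3, 1:3] <- geom$orientation %*% diag(geom$spacing)
  a[1:3, 4] <- geom$origin
  a
}

.as_points <- function(p) {
  if (is.null(dim(p))) matrix(as.numeric(p), ncol = 3) else {
    stopifnot(ncol(p) == 3)
    p
  }
}

#' Map voxel indices to physical mm coordinates
#'
#' @param geom a [geometry()].
#' @param index a length-3 vector or n x 3 matrix of (possibly fractional)
#'   0-based voxel indices.
#' @return physical coordinates, same shape as the input.
#' @seealso [physical_to_voxel()] for the exact inverse.
#' @export
voxel_to_physical <- function(geom, index) {
  ix <- .as_points(index)
  stopifnot(all(is.finite(ix)))
  p <- sweep(ix, 2, geom$spacing, `*`) %*% t(geom$orientation)
  p <- sweep(p, 2, geom$origin, `+`)
  if (is.null(dim(index))) drop(p) else p
}

#' Map physical mm coordinates to fractional voxel indices
#'
#' @inheritParams voxel_to_physical
#' @param point a length-3 vector or n x 3 matrix of physical mm coordinates.
#' @return fractional 0-based voxel indices, same shape as the input.
#' @export
physical_to_voxel <- function(geom, point) {
  pt <- .as_points(point)
  stopifnot(all(is.finite(pt)))
  v <- sweep(pt, 2, geom$origin, `-`) %*% geom$orientation  # t(R^-1) = R
  v <- sweep(v, 2, geom$spacing, `/`)
  if (is.null(dim(point))) drop(v) else v
}
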