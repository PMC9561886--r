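# Rupture side classification: project the rupture point onto the line
# connecting the footprint centres and read off which of its three equal
# thirds the perpendicular foot falls in.

.side_levels <- c("femoral", "middle", "tibial")

#' The ACL axis between the two footprint centres
#'
#' @param femoral_center,tibial_center physical mm 3-vectors.
#' @return object of class `acl_axis` with the two centres and derived `length`
#'   (mm) and unit direction `u` (femoral to tibial).
#' @export
acl_axis <- function(femoral_center, tibial_center) {
  a <- as.numeric(femoral_center); b <- as.numeric(tibial_center)
  v <- b - a
  len <- sqrt(sum(v^2))
  if (!is.finite(len) || len <= 0) stop("zero-length ACL axis")
  structure(list(femoral_center = a, tibial_center = b, length = len,
                 u = v / len), class = "acl_axis")
}

#' Projection fraction of a point along the ACL axis
#'
#' Drops a perpendicular from `point` onto the femoral-tibial line; the foot is
#' `femoral_center + t * length * u`. `t` is clamped to \[0, 1\] so predictions
#' beyond either footprint still receive a class.
#'
#' @param point physical mm 3-vector.
#' @param axis an [acl_axis()].
#' @return scalar t in \[0, 1\].
#' @export
project_fraction <- function(point, axis) {
  stopifnot(inherits(axis, "acl_axis"))
  t <- sum((as.numeric(point) - axis$femoral_center) * axis$u) / axis$length
  min(max(t, 0), 1)
}

#' Side class from a projection fraction
#'
#' The axis is divided into three equal parts: femoral for t <= 1/3, middle for
#' 1/3 < t <= 2/3, tibial for t > 2/3. Boundary values belong to the more
#' femoral class (closed-left convention; ties are measure-zero but must be
#' deterministic).
#'
#' @param t projection fraction in \[0, 1\].
#' @return list with `value` (factor femoral/middle/tibial) and `t`.
#' @export
classify_side <- function(t) {
  stopifnot(is.finite(t), t >= 0, t <= 1)
  v <- if (t <= 1 / 3) "femoral" else if (t <= 2 / 3) "middle" else "tibial"
  list(value = factor(v, levels = .side_levels), t = t)
}

#' Classify a localization result against an ACL axis
#'
#' @param result an `acl_localization` from [decode_heatmap()], [decode_2d()]
#'   or [localize_case()] — or any list with a `point` field.
#' @param axis an [acl_axis()].
#' @return list with `value` and `t`, as [classify_side()].
#' @export
classify_case <- function(result, axis) {
  classify_side(project_fraction(result$point, axis))
}
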