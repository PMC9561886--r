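#' Ground-truth landmarks for one case
#'
#' Holds the rupture point, the femoral and tibial footprint centres (all in
#' physical mm, scanner frame) and the side class derived from them. The side
#' stored here is always recomputed from the geometry via [classify_side()],
#' never supplied independently, so label and coordinates cannot drift apart.
#'
#' @param rupture_point,femoral_center,tibial_center physical mm 3-vectors.
#' @return an object of class `acl_landmarks` with fields `rupture_point`,
#'   `femoral_center`, `tibial_center`, `side` (factor) and `t` (projection
#'   fraction along the femoral to tibial axis).
#' @export
landmark_gt <- function(rupture_point, femoral_center, tibial_center) {
  pts <- lapply(list(rupture_point, femoral_center, tibial_center), as.numeric)
  if (!all(vapply(pts, function(p) length(p) == 3 && all(is.finite(p)), TRUE)))
    stop("landmarks must be finite 3-vectors")
  if (sqrt(sum((pts[[2]] - pts[[3]])^2)) <= 0)
    stop("femoral and tibial centers must differ")
  axis <- acl_axis(pts[[2]], pts[[3]])
  side <- classify_side(project_fraction(pts[[1]], axis))
  structure(list(rupture_point = pts[[1]], femoral_center = pts[[2]],
                 tibial_center = pts[[3]], side = side$value, t = side$t),
            class = "acl_landmarks")
}

#' Write landmark annotations to a TSV file
#'
#' One row per case: `case`, `x`, `y`, `z` (physical mm, scanner LPS frame —
#' annotations are stored in scanner coordinates, not patch-local ones) and
#' `side`.
#'
#' @param gts named list of [landmark_gt()] objects (names are case ids).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(gts, path) {
  df <- do.call(rbind, lapply(names(gts), function(id) {
    g <- gts[[id]]
    data.frame(case = id, x = g$rupture_point[1], y = g$rupture_point[2],
               z = g$rupture_point[3], side = as.character(g$side))
  }))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read landmark annotations from TSV
#'
#' @param path TSV with columns `case`, `x`, `y`, `z` and optionally `side`.
#' @return data.frame of annotations (coordinates in physical mm).
#' @export
read_landmarks <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("case", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("landmark TSV must have columns: ", paste(need, collapse = ", "))
  df
}
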