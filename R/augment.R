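# Data augmentation: random in-plane rotation, axis flips and elastic
# deformation, applied identically to an image, its paired voxel targets and
# the landmark coordinate.

# Trilinear sample of a 3D array at fractional 0-based voxel coords (n x 3),
# clamped to the grid.
.trilinear <- function(arr, coords) {
  d <- dim(arr)
  cx <- pmin(pmax(coords[, 1], 0), d[1] - 1)
  cy <- pmin(pmax(coords[, 2], 0), d[2] - 1)
  cz <- pmin(pmax(coords[, 3], 0), d[3] - 1)
  x0 <- pmin(floor(cx), max(d[1] - 2, 0)); fx <- cx - x0
  y0 <- pmin(floor(cy), max(d[2] - 2, 0)); fy <- cy - y0
  z0 <- pmin(floor(cz), max(d[3] - 2, 0)); fz <- cz - z0
  if (d[1] == 1) { x0 <- fx * 0; fx <- fx * 0 }
  if (d[2] == 1) { y0 <- fy * 0; fy <- fy * 0 }
  if (d[3] == 1) { z0 <- fz * 0; fz <- fz * 0 }
  g <- function(ox, oy, oz)
    arr[cbind(pmin(x0 + ox, d[1] - 1) + 1, pmin(y0 + oy, d[2] - 1) + 1,
              pmin(z0 + oz, d[3] - 1) + 1)]
  g(0, 0, 0) * (1 - fx) * (1 - fy) * (1 - fz) +
    g(1, 0, 0) * fx * (1 - fy) * (1 - fz) +
    g(0, 1, 0) * (1 - fx) * fy * (1 - fz) +
    g(1, 1, 0) * fx * fy * (1 - fz) +
    g(0, 0, 1) * (1 - fx) * (1 - fy) * fz +
    g(1, 0, 1) * fx * (1 - fy) * fz +
    g(0, 1, 1) * (1 - fx) * fy * fz +
    g(1, 1, 1) * fx * fy * fz
}

# Upsample a coarse displacement grid (cp spacing in voxels) to the full grid.
.elastic_field <- function(d, control_spacing, max_disp) {
  nc <- pmax(ceiling((d - 1) / control_spacing) + 1, 2)
  field <- array(0, c(prod(d), 3))
  full <- as.matrix(expand.grid(x = 0:(d[1] - 1), y = 0:(d[2] - 1),
                                z = 0:(d[3] - 1)))
  for (ax in 1:3) {
    coarse <- array(stats::rnorm(prod(nc), 0, max_disp / 2), nc)
    coarse <- pmin(pmax(coarse, -max_disp), max_disp)
    field[, ax] <- .trilinear(coarse, full / control_spacing)
  }
  field
}

#' Apply seeded spatial augmentation to an image and its paired targets
#'
#' The same spatial transform is applied to the image (linear interpolation),
#' any heatmap target (linear), any label target (nearest neighbour) and the
#' landmark voxel coordinate. Supported ops: `"flip"` (random axes), `"rotate"`
#' (random in-plane angle) and `"elastic"` (seeded coarse displacement grid,
#' control-point spacing 8 voxels, maximum displacement 2 voxels). Deterministic
#' for a fixed seed; an empty op set is the identity.
#'
#' @param image 2D matrix or 3D array.
#' @param targets optional named list: elements `heatmap` (array like `image`),
#'   `labels` (integer array like `image`), `landmark` (0-based fractional
#'   voxel coordinate, length 2 or 3).
#' @param ops character subset of `c("rotate", "flip", "elastic")`.
#' @param seed integer seed.
#' @param params optional overrides: `angle` (degrees), `flip_axes` (logical
#'   3-vector). Used for reproducible round-trip checks.
#' @return list with `image`, `targets` (same structure, transformed) and the
#'   sampled `params`.
#' @export
augment <- function(image, targets = list(), ops = c("rotate", "flip"),
                    seed = 1, params = list()) {
  stopifnot(all(ops %in% c("rotate", "flip", "elastic")))
  was2d <- length(dim(image)) == 2
  to3 <- function(a) if (length(dim(a)) == 2) array(a, c(dim(a), 1)) else a
  image <- to3(image)
  d <- dim(image)
  set.seed(seed)
  angle <- if ("rotate" %in% ops) {
    if (!is.null(params$angle)) params$angle else stats::runif(1, -15, 15)
  } else 0
  flip_axes <- if ("flip" %in% ops) {
    if (!is.null(params$flip_axes)) params$flip_axes
    else stats::runif(3) < 0.5
  } else c(FALSE, FALSE, FALSE)
  if (was2d) flip_axes[3] <- FALSE
  field <- if ("elastic" %in% ops) .elastic_field(d, 8, 2) else NULL

  ctr <- (d - 1) / 2
  th <- angle * pi / 180
  # forward map: flip, then rotate about the in-plane centre, then elastic
  fwd <- function(pts) {
    for (ax in 1:3) if (flip_axes[ax]) pts[, ax] <- (d[ax] - 1) - pts[, ax]
    if (th != 0) {
      x <- pts[, 1] - ctr[1]; y <- pts[, 2] - ctr[2]
      pts[, 1] <- ctr[1] + cos(th) * x - sin(th) * y
      pts[, 2] <- ctr[2] + sin(th) * x + cos(th) * y
    }
    if (!is.null(field)) {
      # fixed-point inversion of q = p - u(q): landmarks move with the tissue
      q <- pts
      for (i in 1:8) {
        uu <- vapply(1:3, function(ax)
          .trilinear(array(field[, ax], d), q), numeric(nrow(pts)))
        q <- pts - matrix(uu, ncol = 3)
      }
      pts <- q
    }
    pts
  }
  # inverse map used for resampling: elastic pullback, rotate back, unflip
  inv <- function(pts) {
    if (!is.null(field))
      pts <- pts + matrix(vapply(1:3, function(ax)
        .trilinear(array(field[, ax], d), pts), numeric(nrow(pts))), ncol = 3)
    if (th != 0) {
      x <- pts[, 1] - ctr[1]; y <- pts[, 2] - ctr[2]
      pts[, 1] <- ctr[1] + cos(th) * x + sin(th) * y
      pts[, 2] <- ctr[2] - sin(th) * x + cos(th) * y
    }
    for (ax in 1:3) if (flip_axes[ax]) pts[, ax] <- (d[ax] - 1) - pts[, ax]
    pts
  }

  grid <- as.matrix(expand.grid(x = 0:(d[1] - 1), y = 0:(d[2] - 1),
                                z = 0:(d[3] - 1)))
  src <- inv(grid)
  resample <- function(a, nearest = FALSE) {
    s <- if (nearest) round(src) else src
    array(.trilinear(to3(a), s), d)
  }
  out_img <- resample(image)
  out_t <- targets
  if (!is.null(targets$heatmap)) out_t$heatmap <- resample(targets$heatmap)
  if (!is.null(targets$labels))
    out_t$labels <- array(as.integer(resample(targets$labels, nearest = TRUE)),
                          d)
  if (!is.null(targets$landmark)) {
    lm <- targets$landmark
    lm3 <- if (length(lm) == 2) c(lm, 0) else lm
    out_lm <- drop(fwd(matrix(lm3, 1)))
    out_t$landmark <- if (length(lm) == 2) out_lm[1:2] else out_lm
  }
  strip <- function(a) if (was2d) array(a, d[1:2]) else a
  list(image = strip(out_img),
       targets = within_list(out_t, was2d, strip),
       params = list(angle = angle, flip_axes = flip_axes))
}

# apply strip() to array-valued target entries when the input was 2D
within_list <- function(tl, was2d, strip) {
  if (!was2d) return(tl)
  for (nm in intersect(names(tl), c("heatmap", "labels")))
    tl[[nm]] <- strip(tl[[nm]])
  tl
}
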