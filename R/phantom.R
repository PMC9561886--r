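# Synthetic knee phantoms: a bright ACL-like tube spanning two footprint
# spheres, with a signal gap at a controllable fraction along the tube. Every
# downstream stage (segmentation targets, heatmap regression, decoding,
# classification, statistics) is exercised end-to-end on these without any
# patient data.

#' Specification of a synthetic ACL phantom
#'
#' Defaults follow ACL anatomy (tube about 38 mm long and 11 mm wide) on a
#' 64x64x32 grid at (1, 1, 3) mm spacing — sagittal-like anisotropy with
#' roughly 3 mm slices, small enough to train desk-scale networks on a CPU.
#'
#' @param grid_shape integer 3-vector, voxels per axis.
#' @param spacing mm per voxel per axis.
#' @param acl_length tube length in mm (femoral to tibial footprint centre).
#' @param acl_width tube diameter in mm.
#' @param footprint_radius radius (mm) of the footprint spheres at either end.
#' @param rupture_fraction position t in (0, 1) of the signal gap along the
#'   femoral-to-tibial chord.
#' @param gap_halfwidth half-extent (mm) of the gap along the chord.
#' @param noise_sd additive Gaussian noise sd, intensity units.
#' @param tube_intensity,footprint_intensity,background_intensity intensities.
#' @return object of class `acl_phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 32), spacing = c(1, 1, 3),
                         acl_length = 38, acl_width = 11, footprint_radius = 6,
                         rupture_fraction = 0.5, gap_halfwidth = 3,
                         noise_sd = 0.05, tube_intensity = 1,
                         footprint_intensity = 0.8, background_intensity = 0) {
  spec <- list(grid_shape = as.integer(grid_shape), spacing = as.numeric(spacing),
               acl_length = acl_length, acl_width = acl_width,
               footprint_radius = footprint_radius,
               rupture_fraction = rupture_fraction,
               gap_halfwidth = gap_halfwidth, noise_sd = noise_sd,
               tube_intensity = tube_intensity,
               footprint_intensity = footprint_intensity,
               background_intensity = background_intensity)
  if (spec$rupture_fraction <= 0 || spec$rupture_fraction >= 1)
    stop("rupture_fraction must lie strictly inside (0, 1)")
  if (!(spec$acl_length > 2 * spec$gap_halfwidth) || spec$gap_halfwidth <= 0)
    stop("need acl_length > 2 * gap_halfwidth > 0")
  if (spec$noise_sd < 0) stop("noise_sd must be >= 0")
  if (any(spec$grid_shape < 2) || any(spec$spacing <= 0))
    stop("invalid grid")
  structure(spec, class = "acl_phantom_spec")
}

# Uniform direction on the sphere.
.runif_dir <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-8) return(v / n)
  }
}

#' Generate one synthetic phantom case
#'
#' A cylinder of diameter `acl_width` spans two footprint spheres along a
#' seeded random chord of length `acl_length`, both endpoints kept at least
#' `footprint_radius` from the grid border. Intensities within
#' `gap_halfwidth` of the point at `rupture_fraction` along the chord are reset
#' to background, then Gaussian noise is added. The ground-truth side class is
#' derived from the geometry by the thirds rule, never stored independently.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed; output is deterministic in (spec, seed).
#' @return object of class `acl_phantom_case`: fields `volume` ([volume()]),
#'   `labels` ([label_map()]; 0 background, 1 femoral footprint, 2 tibial
#'   footprint, 3 ACL tube) and `gt` ([landmark_gt()]).
#' @examples
#' case <- generate_phantom(phantom_spec(noise_sd = 0), seed = 1)
#' case$gt$side
#' @export
generate_phantom <- function(spec, seed) {
  stopifnot(inherits(spec, "acl_phantom_spec"))
  set.seed(seed)
  ext <- (spec$grid_shape - 1) * spec$spacing
  lo <- rep(spec$footprint_radius, 3)
  hi <- ext - spec$footprint_radius
  if (any(hi - lo < 0)) stop("tube does not fit in grid")
  half <- spec$acl_length / 2
  ok <- FALSE
  for (try in 1:1000) {
    d <- .runif_dir()
    span_lo <- lo + pmax(half * d, -half * d)   # |d_i| * half
    span_hi <- hi - pmax(half * d, -half * d)
    if (all(span_hi >= span_lo)) {
      ctr <- stats::runif(3, span_lo, span_hi)
      a <- ctr - half * d
      b <- ctr + half * d
      ok <- TRUE
      break
    }
  }
  if (!ok) stop("tube does not fit in grid")
  geom <- geometry(spacing = spec$spacing)
  n <- spec$grid_shape
  px <- (seq_len(n[1]) - 1) * spec$spacing[1]
  py <- (seq_len(n[2]) - 1) * spec$spacing[2]
  pz <- (seq_len(n[3]) - 1) * spec$spacing[3]
  PX <- array(px, n); PY <- array(rep(py, each = n[1]), n)
  PZ <- array(rep(pz, each = n[1] * n[2]), n)
  dxa <- PX - a[1]; dya <- PY - a[2]; dza <- PZ - a[3]
  s <- dxa * d[1] + dya * d[2] + dza * d[3]       # chord coordinate, mm
  da2 <- dxa^2 + dya^2 + dza^2
  sc <- pmin(pmax(s, 0), spec$acl_length)
  dseg2 <- da2 - 2 * s * sc + sc^2                # |p-a|^2 - 2 s sc + sc^2
  db2 <- da2 - 2 * s * spec$acl_length + spec$acl_length^2
  fem <- da2 <= spec$footprint_radius^2
  tib <- db2 <= spec$footprint_radius^2
  tube <- dseg2 <= (spec$acl_width / 2)^2 & !fem & !tib
  labels <- array(0L, n)
  labels[tube] <- 3L; labels[fem] <- 1L; labels[tib] <- 2L
  # the rupture severs everything within the tube radius, footprint overlap
  # included: near-footprint gaps must stay visible
  gap <- dseg2 <= (spec$acl_width / 2)^2 &
    abs(s - spec$rupture_fraction * spec$acl_length) <= spec$gap_halfwidth
  intens <- array(spec$background_intensity, n)
  intens[fem | tib] <- spec$footprint_intensity
  intens[tube] <- spec$tube_intensity
  intens[gap] <- spec$background_intensity
  if (spec$noise_sd > 0)
    intens <- intens + array(stats::rnorm(prod(n), 0, spec$noise_sd), n)
  gt <- landmark_gt(a + spec$rupture_fraction * spec$acl_length * d, a, b)
  structure(list(volume = volume(intens, geom),
                 labels = label_map(labels, geom),
                 gt = gt, spec = spec, seed = seed),
            class = "acl_phantom_case")
}

#' Generate a phantom dataset with controlled side proportions
#'
#' Side counts follow `fraction_per_side` (femoral, middle, tibial) with
#' largest-remainder rounding; each case's `rupture_fraction` is drawn
#' uniformly within its side's third of the axis. The default proportions
#' mirror a realistic clinical imbalance of 43:35:7.
#'
#' @param n number of cases.
#' @param spec base [phantom_spec()]; `rupture_fraction` is overridden per case.
#' @param seed integer seed for the whole dataset.
#' @param fraction_per_side three proportions summing to 1.
#' @return named list of `acl_phantom_case` (ids `case001`, ...).
#' @export
make_dataset <- function(n, spec = phantom_spec(), seed = 1,
                         fraction_per_side = c(43, 35, 7) / 85) {
  p <- as.numeric(fraction_per_side)
  stopifnot(length(p) == 3, all(p >= 0))
  if (abs(sum(p) - 1) > 1e-9) stop("proportions must sum to 1")
  counts <- floor(n * p)
  rem <- n * p - counts
  short <- n - sum(counts)
  if (short > 0) {
    give <- order(rem, decreasing = TRUE)[seq_len(short)]
    counts[give] <- counts[give] + 1
  }
  if (n < sum(p > 0))
    stop("cannot realize all nonzero side proportions with n = ", n)
  set.seed(seed)
  thirds <- rbind(c(0, 1 / 3), c(1 / 3, 2 / 3), c(2 / 3, 1))
  side_idx <- rep(1:3, counts)[sample.int(n)]  # mix sides across the list
  tvals <- stats::runif(n, thirds[side_idx, 1], thirds[side_idx, 2])
  case_seeds <- sample.int(2147483646L, n)
  cases <- lapply(seq_len(n), function(i) {
    si <- spec
    si$rupture_fraction <- tvals[i]
    generate_phantom(si, case_seeds[i])
  })
  names(cases) <- sprintf("case%03d", seq_len(n))
  cases
}

#' Simulate a clinical reader's rupture annotation
#'
#' Emulates a reader placing a patch at the believed rupture site: the returned
#' patch centroid is the true rupture point plus a systematic per-axis bias and
#' seeded Gaussian jitter. `patch_halfwidth` records the patch half-extent a
#' reader would draw; the centroid of a symmetric patch is its centre, so it
#' does not alter the returned coordinate.
#'
#' @param gt an [landmark_gt()].
#' @param bias mm 3-vector of systematic offset.
#' @param sd per-axis jitter sd in mm (>= 0).
#' @param patch_halfwidth patch half-extent in mm (bookkeeping only).
#' @param seed integer seed.
#' @return physical mm 3-vector: the annotated patch centroid.
#' @export
simulate_reader <- function(gt, bias = c(0, 0, 0), sd = 0, patch_halfwidth = 5,
                            seed = 1) {
  stopifnot(sd >= 0)
  set.seed(seed)
  gt$rupture_point + as.numeric(bias) + stats::rnorm(3, 0, sd)
}

#' Write a phantom dataset to disk
#'
#' Per case: `<id>_volume.nii.gz`, `<id>_labels.nii.gz`; plus `landmarks.tsv`
#' (scanner-frame mm coordinates) and `manifest.tsv` listing ids, seeds,
#' rupture fractions and sides. Optionally also a DICOM series per case.
#'
#' @param cases named list from [make_dataset()] (or a single case in a list).
#' @param dir output directory.
#' @param dicom also export each volume as a DICOM series under `<id>_dicom/`.
#' @return the manifest as a data.frame, invisibly.
#' @export
write_phantom_dataset <- function(cases, dir, dicom = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(names(cases), function(id) {
    cs <- cases[[id]]
    write_volume(cs$volume, file.path(dir, paste0(id, "_volume.nii.gz")))
    write_volume(cs$labels, file.path(dir, paste0(id, "_labels.nii.gz")))
    if (dicom)
      write_dicom_series(quantize_intensities(cs$volume),
                         file.path(dir, paste0(id, "_dicom")))
    data.frame(case = id, seed = cs$seed,
               rupture_fraction = cs$spec$rupture_fraction,
               side = as.character(cs$gt$side))
  })
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  write_landmarks(lapply(cases, `[[`, "gt"), file.path(dir, "landmarks.tsv"))
  invisible(manifest)
}
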