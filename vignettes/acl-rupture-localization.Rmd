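---
title: "Localizing and classifying ACL ruptures: models, phantoms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Localizing and classifying ACL ruptures: models, phantoms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A ruptured anterior cruciate ligament (ACL) can sometimes be repaired rather
than reconstructed, but the choice hinges on *where* along the ligament the
tear sits. The ACL runs roughly 38 mm between its femoral and tibial
attachment areas (the *footprints*) and is about 11 mm wide. A clinically
useful simplification divides the femoral-to-tibial line into three equal
parts: a tear whose perpendicular projection falls in the first third is
*femoral-side* (a repair candidate), in the middle third *middle*, and in the
last third *tibial-side*.

`aclloc` implements a fully automated pipeline that takes a 3D knee MR volume
and returns the rupture point in scanner coordinates plus its side class,
together with the complete statistical machinery used to evaluate such a
system against clinical readers. Because no public imaging dataset accompanies
this problem, the package also ships a synthetic phantom generator so that
every stage — training included — is exercisable end to end.

## The pipeline

The cascade has three stages, mirroring a coarse-to-fine design:

1. **Segmentation / ROI.** A 3D encoder–decoder network (or, in oracle mode,
   the ground-truth label map) labels background, femoral footprint, tibial
   footprint and ACL tissue. The ROI is the bounding box of all foreground
   classes dilated by a margin (default 6 mm); the per-class voxel centroids
   give the footprint centres that later define the classification axis. An
   empty footprint class is treated as a hard failure for that case, never
   silently patched.

2. **Localization.** Two interchangeable routes:
   - *3D heatmap regression* (the primary route): a full-resolution
     encoder–decoder with strided-convolution downsampling, transpose
     convolution upsampling, skip concatenation, group normalization and a
     sigmoid output channel predicts a per-voxel probability field. At
     inference the field is thresholded at 0.5 and the probability-weighted
     centroid of the suprathreshold region, mapped through the patch
     geometry, is the rupture point.
   - *2D slice selection + keypoint detection*: a slab of 6 slices resampled
     to 0.25 mm in-plane is scored by a slice-selection net built from
     1×3×3 convolutions and in-plane max pooling (for a 256×256 input:
     nine convolution sets, eight pools, so the plane collapses 256 → 1 while
     the 6 slices never mix), and a single-level detector predicts one box on
     the chosen slice whose centre is the in-plane keypoint.

3. **Classification.** The rupture point is projected onto the line from the
   femoral to the tibial footprint centre; the projection fraction
   `t` (clamped to [0, 1]) is cut at 1/3 and 2/3 into femoral / middle /
   tibial.

## Training targets

The heatmap target is a 3D Gaussian centred at the annotated rupture point,
rescaled so the voxel containing the landmark is exactly 1, truncated at a
support radius, and surrounded by a *false-positive suppression band*: a
shell of voxels that are neither positive targets nor trusted negatives and
are excluded from the loss entirely. The training loss is a combination of
soft Dice and focal loss computed over valid voxels only; perturbing
predictions inside the band cannot change the loss, which the tests verify to
machine precision. For multi-class segmentation targets the Dice term is
computed per class and averaged, so the small footprint classes are not
swamped by the background class.

Key parameters (all configurable, defaults chosen once):

| parameter | default | rationale |
|---|---|---|
| `sigma` | 3 mm | comparable to slice thickness; support stays well inside a 12 mm class third |
| `support_radius` | 3·sigma | standard truncation, < 1.2% residual mass |
| `suppression_band` | 2 mm | typical scale at which near-landmark voxels stop being trustworthy negatives; placed as a shell immediately *outside* the support, because suppressing inside it would erase the target itself |
| `dice_weight`, `focal_weight` | 1, 1 | unweighted combination; no canonical weighting exists |
| `focal_gamma`, `focal_alpha` | 2, 0.25 | the standard focal-loss defaults |
| failure threshold | 10 mm, strict `>` | exactly 10.0 mm still counts as a success |

The slice-selection target supervises the two integer slices straddling the
landmark's fractional slice coordinate; the straddle pair is forced by the
geometry, while splitting their weights linearly by the fractional part is a
design choice that preserves sub-slice information under cross-entropy. At inference the argmax slice is used (lowest index on ties,
flagged low-confidence), not a weighted combination.

Augmentation (random in-plane rotation, axis flips, elastic deformation from
a coarse displacement grid with 8-voxel control spacing and 2-voxel maximum
displacement) applies one spatial transform consistently to image, voxel
targets and landmark coordinates; flips are exact involutions and rotation
round-trips restore landmarks to within 0.1 voxel.

## Coordinate conventions

All physical coordinates are millimetres in the LPS frame (DICOM convention);
NIfTI RAS headers are converted on read and write. Voxel indices are 0-based
and fractional indices are legal everywhere, so sub-voxel centroids share the
same algebra as grid points. Cropping updates the origin so every retained
voxel keeps its physical position; in-plane resampling (linear for
intensities, nearest for labels) preserves the physical extent within one
voxel. DICOM series are sorted by position projected on the slice normal —
never by filename — and a mixed-series directory or slice spacing that varies
by more than 1e-3 mm is an error.

## The phantom: what it does and does not emulate

Each phantom is a 64×64×32 grid at (1, 1, 3) mm — sagittal-like anisotropy —
containing a bright tube of length 38 mm and width 11 mm spanning two
footprint spheres along a seeded random chord, with a signal gap (intensity
reset to background over ±3 mm along the chord) at a controllable fraction
`t`, plus additive Gaussian noise (sd 0.05 against a tube contrast of 1.0).
Datasets draw `t` uniformly within each side's third, with side counts
following a 43:35:7 femoral:middle:tibial imbalance by largest-remainder
rounding, mirroring a realistic clinical cohort; the case order is then
shuffled so sequential splits stay class-mixed. The side label is always
*derived* from the geometry by the thirds rule, never stored independently,
so labels cannot drift from coordinates.

What the phantom does **not** emulate: anatomy beyond a tube (the real knee
has four-plus relevant structures), Rician MR noise, partial tears, field
inhomogeneity, or reader disagreement about what counts as the rupture
centre. Passing phantom tests therefore demonstrates that the pipeline's
machinery — geometry, targets, optimization, decoding, classification,
statistics — is correct and trainable, not that clinical-cohort
accuracies transfer; those require the original patient data, which is not
deposited.

Simulated readers (ground truth plus per-axis bias and Gaussian jitter) feed
the agreement statistics; with jitter sd σ per axis the mean annotation error
is σ·√(8/π) mm, which the tests verify by Monte Carlo.

## Networks at desk scale

Clinical-scale systems for this task train full nnU-Net-class models on
multi-GPU hardware; this package deliberately runs at desk scale on one CPU. The heatmap and
segmentation nets default to depth 3 with 8 base channels (~120k parameters),
convolutions are im2col + BLAS matrix products with exact hand-derived
backward passes (validated by finite differences in the test suite), and
optimization is plain momentum SGD, batch of one, fully deterministic given a
seed. `norm = "batch"` is honoured as per-channel statistics of the current
(single-sample) batch, i.e. instance-style normalization — with batch size
one that is what batch statistics reduce to.

The localization net operates on a fixed 48×48×16-voxel patch cropped around
the ROI centre and resampled in-plane to 1.5 mm (a 32×32×16 input covering a
48×48×48 mm field of view). Training and inference share this exact patch
pipeline. Problem sizes used by the bundled experiments — 60 training and 20
held-out phantoms, 15 epochs — were chosen so a full parameter-recovery run
completes in minutes on one core; under those conditions the trained net
localizes held-out ruptures to about 1 mm mean error with no failures at the
10 mm rule and classifies sides with accuracy ≥ 0.95, and the training loss
falls by more than half.

The detector backbone is a small strided conv stack rather than a pretrained
ResNet-101 (pretrained weights are out of scope); the box size is fixed at
the ACL width equivalent, since the keypoint is read off the box centre and
no size supervision exists beyond that convention.

## Evaluation machinery

Metrics follow the standard one-vs-rest reduction of the 3×3 confusion matrix
(rows predicted, columns true): per class, sensitivity TP/(TP+FN),
specificity TN/(TN+FP), precision TP/(TP+FP), F1 = TP/(TP+0.5(FP+FN)) — the
algebraic twin of the harmonic mean, which the tests confirm on random
matrices — and overall accuracy trace/total. Metrics with zero denominators
are reported as `NA`, never as 0 or 1: reader matrices can be extremely
sparse and silent zeros would mislead. Inter-rater agreement uses ICC(2,1)
(two-way random effects, absolute agreement, single measure) with the
standard F-based confidence interval, computed on a per-case scalar — by
default the Euclidean distance of each reader's annotation from a common
reference, since no convention exists for which scalar the agreement should
be computed on and distances are the quantity the study design actually
compares. Group comparisons use the classical one-way ANOVA. Both ICC and
ANOVA are checked against explicit sums-of-squares oracles.

The bundled `acl_reader_confusions()` matrices are a reference
benchmark for this exact task. One bookkeeping quirk is preserved as printed:
the second resident's matrix records 84 of the 85 cases, so its overall
accuracy recomputes as 36/84 = 0.43 rather than the 0.42 that results from
dividing by the full cohort; all of its per-class metrics reproduce exactly
from the 84-case matrix.

## Numerical and design choices

- **Thirds boundaries** are closed on the left (t = 1/3 is femoral,
  t = 2/3 is middle): ties are measure-zero but must be deterministic.
- **Out-of-segment projections clamp** to [0, 1] rather than erroring:
  a badly localized prediction must still receive a class, as failure
  statistics handle the rest.
- **Weighted vs binary centroid**: the decoder defaults to the
  probability-weighted centroid for sub-voxel stability; the unweighted
  variant is exposed (`centroid = "binary"`).
- **Empty threshold set**: the decoder falls back to the global maximum
  (first in scan order on ties) and flags `fallback_used`, so failure
  statistics stay honest rather than crashing or hiding.
- **Slice-net pooling axes**: a literal reading of "downsampling on the
  slice size" conflicts with preserving 6 slices through 8 pools; pooling is
  applied to the in-plane dimensions only, the only interpretation consistent
  with a 256 → 1 collapse and a 6-long output.
- **Footprint centres at inference** come from segmentation centroids, not
  manual input, preserving full automation; a label-map override exists.
- **Landmark annotations on disk** are scanner-frame physical millimetres
  (not patch-local), recorded as such in the TSV format.
- **DICOM export quantizes** to the 16-bit stored-value grid first
  (`quantize_intensities()`, slope 2^-10), so DICOM and NIfTI round trips
  agree to 1e-6 instead of silently differing by quantization error.

## Limitations

The networks are desk-scale by design: they demonstrate trainability and
parameter recovery on phantoms, not clinical performance. The DICOM support
covers explicit-VR little-endian single-frame series (what the phantom
exporter writes) and rejects everything else loudly. Elastic augmentation
inverts the displacement field by fixed-point iteration, which is approximate
for extreme deformations. Partial tears, multi-rupture cases and tissue
quality grading are out of scope.
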