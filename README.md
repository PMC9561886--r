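# aclloc — automated ACL rupture localization and side classification

`aclloc` is an R toolkit for localizing the rupture point of the anterior
cruciate ligament (ACL) in 3D knee MR volumes and classifying the tear as
**femoral-side**, **middle** or **tibial-side** — the distinction that
determines whether a tear is a candidate for primary repair rather than
reconstruction. It is aimed at medical-image-analysis researchers who want a
fully inspectable, CPU-scale reimplementation of a coarse-to-fine deep
learning localization pipeline, together with the complete evaluation
statistics used in reader studies, and a synthetic phantom generator that
makes every stage testable without patient data.

## The method

The pipeline is a cascade:

1. **Segmentation → ROI.** A 3D encoder–decoder network labels the femoral
   footprint, tibial footprint and ACL tissue; the region of interest is the
   dilated bounding box of the foreground, and the per-class centroids give
   the footprint centres.
2. **Localization** by 3D heatmap regression: the network is trained against
   a Gaussian target centred on the annotated rupture point `p*`,

   `h(v) = exp(−‖x(v) − p*‖² / 2σ²)`,   rescaled so the landmark voxel is 1,

   truncated at `3σ`, and surrounded by a *false-positive suppression band*
   (default 2 mm) of voxels excluded from the loss entirely. The loss is
   `L = w_d (1 − softDice) + w_f mean(focal)` over valid voxels. At inference
   the predicted field is thresholded at 0.5 and the probability-weighted
   centroid of the suprathreshold region is the rupture point. A 2D
   alternative (slice-selection net over a 6-slice slab resampled to 0.25 mm
   in-plane, plus a single-level box detector whose centre is the keypoint)
   is also provided.
3. **Classification.** With footprint centres `f` (femoral) and `t` (tibial),
   the projection fraction of a point `p` is

   `t̂ = clamp(⟨p − f, u⟩ / ‖t − f‖, 0, 1)`, `u = (t − f)/‖t − f‖`,

   and the side is femoral if `t̂ ≤ 1/3`, middle if `1/3 < t̂ ≤ 2/3`, tibial
   otherwise. A localization counts as a **failure** when the error exceeds
   10 mm (strictly).

Evaluation: per-class one-vs-rest sensitivity/specificity/precision/F1 with
`F1 = TP/(TP + 0.5(FP+FN))`, overall accuracy, localization error
mean ± sd with failure rate, ICC(2,1) inter-rater agreement with F-based
confidence intervals, one-way ANOVA, and seeded k-fold cross-validation.

The networks (3D U-Net-style segmentation and heatmap regression, the slice
net, the detector) are implemented directly in R on an im2col + BLAS
convolution core with exact hand-derived backward passes — no external deep
learning framework — and train deterministically on a single CPU at
desk scale (depth 3, 8 base channels by default).

## Worked example

Generate a phantom cohort, train the heatmap regressor on 60 cases, and
evaluate on 20 held-out cases:

```r
library(aclloc)

res <- run_pipeline(n_train = 60, n_test = 20, seed = 7,
                    train_cfg = train_config(epochs = 15, lr = 0.03, seed = 7))
print(res$stats)
#> localization: 0.48 +/- 0.21 mm, error rate 0.0% (0/20)
print(res$metrics)
#>     class sensitivity specificity precision f1
#> 1 femoral           1           1         1  1
#> 2  middle           1           1         1  1
#> 3  tibial           1           1         1  1
#> overall accuracy: 1.00 (n = 20)
round(res$history, 2)
#>  [1] 0.79 0.48 0.23 0.12 0.10 0.06 0.07 0.07 0.05 0.05 0.04 0.03 0.03 0.03 0.03
```

The held-out rupture points are recovered to half a millimetre on average
(well under the 10 mm failure threshold), every side class is correct, and
the Dice+focal training loss falls by ~96%. The same run is available from
the shell as `exec/aclloc demo --seed 7`.

Benchmark metrics from a reference ACL reader study ship with the package:

```r
m <- class_metrics(acl_reader_confusions()$cnn3d)
print(m)
#>     class sensitivity specificity precision   f1
#> 1 femoral        0.86        0.79      0.80 0.83
#> 2  middle        0.71        0.84      0.76 0.74
#> 3  tibial        0.71        0.99      0.83 0.77
#> overall accuracy: 0.79 (n = 85)
```

## Layout

- `R/` — geometry and volume IO (NIfTI, DICOM series), phantom generator,
  training targets and augmentation, the conv-net core and builders,
  losses and training, decoding and classification, evaluation statistics,
  pipeline orchestration.
- `src/` — Rcpp kernels (im2col/col2im, max pooling).
- `exec/aclloc` — command-line front end (`phantom`, `train-seg`,
  `train-loc`, `localize`, `classify`, `evaluate`, `crossval`, `demo`).
- `vignettes/acl-rupture-localization.Rmd` — the methods vignette: model
  assumptions, parameter choices, phantom realism and limitations.
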