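Package: aclloc
Title: Automated Localization and Side Classification of ACL Ruptures in Knee MR Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A coarse-to-fine toolkit for localizing anterior cruciate ligament
    (ACL) rupture points in 3D knee MR volumes and classifying them as femoral,
    middle or tibial. Provides volumetric IO with full voxel/physical coordinate
    geometry (NIfTI and DICOM series), synthetic knee phantom generation with
    known footprints and a controllable rupture gap, Gaussian heatmap training
    targets with a false-positive suppression band, desk-scale trainable
    convolutional networks (3D encoder-decoder segmentation and heatmap
    regression, 2D slice selection and single-level keypoint detection) with a
    combined Dice and focal loss, centroid-based heatmap decoding, a geometric
    thirds classifier along the femoral-tibial footprint axis, and the complete
    evaluation stack: localization error statistics with a 10 mm failure rule,
    one-vs-rest confusion-matrix metrics, ICC(2,1) inter-rater agreement,
    one-way ANOVA and k-fold cross-validation bookkeeping.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    Rcpp,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    png,
    jsonlite
Config/testthat/edition: 3
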