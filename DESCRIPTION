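Package: vsseg
Title: Automatic Vestibular Schwannoma Segmentation on T1-Weighted MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fully automatic segmentation of vestibular schwannomas on
    contrast-enhanced near-isotropic T1-weighted MR volumes using a residual
    3D U-Net with supervised spatial attention and deep supervision.
    Provides NIfTI volume input/output with voxel-spacing-aware resampling,
    a synthetic head-phantom generator with paired tumor masks for
    framework-free testing, multi-scale Dice training with Adam and a
    piecewise-constant learning-rate schedule, overlapping sliding-window
    whole-volume inference, and volumetric evaluation by Dice similarity
    coefficient, 95th-percentile Hausdorff distance, average symmetric
    surface distance and relative absolute volume difference, with
    tumor-volume-stratified cohort summaries. All network primitives
    (3D convolution, transpose convolution, normalization, backpropagation)
    are implemented natively in compiled code.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
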