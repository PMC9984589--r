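Package: repseg
Title: Repeatability Analysis of Repeated 3D Muscle Segmentations
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify the intra-operator repeatability of manual 3D
    muscle segmentations on clinical MRI. Provides landmark-based affine
    morphing of atlas muscle attachment points (SVD least squares, with
    snap-to-bone correction), decomposition of each segmentation into ten
    nested sub-volumes by paired cutting planes moved along the muscle
    origin-insertion axis in 5% steps, agreement metrics (Jaccard index,
    maximal Hausdorff distance, normalized volume variance) averaged over all
    repetition pairs, and a normality-gated repeated-measures statistical
    layer (one-way RM-ANOVA or Friedman omnibus, Bonferroni-corrected paired
    t or Wilcoxon post hoc, Shrout-Fleiss intraclass correlation). A
    synthetic phantom generator emulates T1-weighted label stacks with
    spatially correlated, extremity-weighted boundary noise so the whole
    pipeline is testable end-to-end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    EBImage,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: ImageProcessing, Segmentation, StatisticalMethod
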