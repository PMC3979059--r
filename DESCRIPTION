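Package: osteomorph
Title: MicroCT Bone Morphometry and Focal-Erosion Surface Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantitative analysis of calibrated micro computed tomography
    (microCT) volumes of bone. Implements the standard murine workflow of
    Gaussian noise filtering, fixed-threshold segmentation on the
    hydroxyapatite density scale, slab- and mask-based region-of-interest
    selection, and three-dimensional morphometry (bone volume fraction,
    triangulated iso-surface bone area, model-independent trabecular and
    cortical thickness, marrow volume), together with surface statistics for
    focal periarticular erosion: the surface density BS/BV and a smoothness
    estimator defined as the ratio of the bone surface recomputed after
    strong Gaussian smoothing to the original bone surface. A synthetic
    phantom generator supplies calibrated volumes with known geometry,
    scanner-like noise and group-level skeletal effects for validation, and
    group comparisons are provided via one-way ANOVA with Tukey's post hoc
    test and the Mann-Whitney test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    jsonlite,
    yaml,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
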