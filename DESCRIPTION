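Package: femablate
Title: Biomechanical Registration and Quantification of Focal Ablation
    Changes in Prostate MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Spatially aligns pre- and post-treatment prostate MRI and isolates
    the shape change induced by focal laser ablation. A mutual-information
    linear registration removes patient-positioning differences; a hexahedral
    linear-elastic finite element model driven by bladder and rectum surface
    correspondences removes organ-motion deformation; a second prostate-surface
    finite element model estimates the residual treatment deformation. Includes
    a synthetic pelvic phantom generator with ground-truth finite element
    deformations, quantification of Dice overlap, organ volume change,
    deformation heatmaps and relative intensity-difference maps, and the
    synthetic inversion-accuracy experiment with its Young's modulus sweep.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    RNifti,
    jsonlite,
    methods,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
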