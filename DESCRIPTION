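Package: mmdir
Title: Multi-Metric Deformable Image Registration for Post-Operative CT
Version: 0.1.0
Authors@R: person("mmdir", "developers", role = c("aut", "cre"),
    email = "mmdir@example.org")
Description: B-spline free-form deformable registration of pre-operative and
    post-operative (planning) CT volumes driven by a weighted combination of
    three cost terms: a fiducial metric (mean Euclidean distance between
    paired landmarks), a region overlap metric (Kappa statistic on binary
    regions of interest), and mutual information between image intensities.
    Includes an affine initialization stage, a three-level Gaussian pyramid
    with control-grid refinement, stochastic gradient descent optimization,
    automatic landmark and region extraction (3D Harris corners, Otsu
    thresholding, normalized cross-correlation point matching), evaluation
    tools (target registration error by tissue group, Dice, Hausdorff,
    checkerboard and orange/cyan overlay renderings), contour propagation
    with margin expansion limited by the skin surface, and a synthetic
    resection-phantom generator with ground-truth deformations so the whole
    pipeline is testable without patient data. Volumes are read and written
    as MetaImage (.mha/.mhd) or NIfTI-1 (.nii/.nii.gz) files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
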