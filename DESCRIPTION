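Package: lungseg
Title: Three-Stage Deep Segmentation of Lung Regions in Thoracic CT Slices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segmentation of the lung parenchyma from axial thoracic CT
    slices using a three-stage system: a slice-gating convolutional
    classifier and quality-gated contrast enhancement (pre-processing), a
    U-net binarizer with candidate-lung-region extraction (processing), and
    contour-quality-gated deep contour refinement with component-level
    false-positive filtering (post-processing).  Includes the classical
    operators the system composes (Otsu thresholding, k-means label
    generation, connected components, Canny edges, hole filling, the
    contour-quality statistic and the Dice coefficient), factories for the
    five training-data configurations of the segmentation U-net and for the
    classifier and refinement networks, a small CPU conv-net engine, and a
    seeded synthetic thorax-phantom generator with exact ground-truth masks
    so the whole system trains and evaluates at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    png,
    tiff,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
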