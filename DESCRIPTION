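Package: busseg
Title: Triple-Branch Breast-Ultrasound Lesion Segmentation with Adaptive
    Fusion, Boundary-Aware Loss and Quantitative Explainability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a hybrid convolutional / selective state-space /
    self-attention encoder for lesion segmentation in grayscale breast
    ultrasound, with per-level adaptive feature fusion, a dense nested
    decoder, and a boundary-aware composite loss (weighted binary
    cross-entropy + Dice + boundary band term).  Ships a seedable speckle
    phantom generator, a cross-validation and ablation harness, per-image
    segmentation metrics (Dice, IoU, boundary IoU, HD95) with a paired
    statistical comparison battery, and a quantitative explainability layer
    (CAM-family and gradient attributions, kernel SHAP/LIME over
    superpixels, attention rollout, Monte-Carlo-dropout uncertainty, and
    attribution-localization statistics such as the normalized energy
    attribution ratio).  All model computation runs on a small built-in
    reverse-mode automatic-differentiation engine with compiled kernels, so
    the package is self-contained on CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    png,
    jsonlite,
    yaml,
    optparse,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
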