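Package: cxrpretext
Title: Modality-Specific Pretext Learning for Chest Radiograph Classification
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for self-supervised, modality-specific pretext learning on
    grayscale chest radiographs. Simulates Gaussian noise and blur
    degradations, trains a VGG-16 Sharp-U-Net restorer with an SSIM objective,
    transfers the restorer encoder to a binary normal-versus-abnormal
    classifier, and fuses classifiers by simple averaging, SLSQP-weighted
    averaging, and a learnable attention-fuzzy ensemble. Includes
    full-reference image-quality metrics (PSNR, SSIM, HaarPSI),
    confusion-matrix classification metrics, confidence-interval based
    sensitivity significance testing, Score-CAM weak localization, a synthetic
    chest-phantom cohort generator, and a pipeline orchestrator, all runnable
    at desk scale on a single CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    jpeg,
    nloptr,
    yaml,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
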