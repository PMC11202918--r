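Package: fundusHSI
Title: Hyperspectral Conversion, Band Selection and Classification of Fundus Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a glaucoma-screening image pipeline: conversion of RGB
    fundus photographs to hyperspectral reflectance cubes via 24-patch
    color-checker calibration (gray-world white balance, Bradford chromatic
    adaptation, PCA reflectance basis with ridge-regularized polynomial
    regression), selection of a discriminative wavelength interval with a
    per-wavelength SNR-difference statistic and its peak structure,
    reconstruction of band-limited images, optic-disc localization with a
    frozen-backbone bounding-box regressor, and two-class classification with
    a frozen Vision Transformer feature extractor and a trainable dense head.
    Includes a synthetic fundus-phantom generator with a planted
    discriminative wavelength interval so the whole pipeline is testable
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    cluster,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
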