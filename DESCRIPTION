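Package: fecalspec
Title: Multispectral Fluorescence Imaging Analysis for Fecal Contamination
    Screening on Poultry Carcasses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting fecal contamination on poultry carcasses from
    line-scan multispectral fluorescence images (27 bands, 410-690 nm).
    Provides a seeded synthetic scene generator with ground truth, ENVI and
    TIFF spectral-cube input/output, spectral preprocessing (multiplicative
    scatter correction, Savitzky-Golay derivatives), PCA and PLS-DA
    chemometric models with leave-one-out cross-validation and kappa
    statistics, chemical-image classification (band ratios, principal
    component score images, regression-coefficient projections), histogram
    auto-thresholding (Shanbhag and Huang fuzzy methods), spot detection
    against ground truth, and an orchestration layer for the spectral,
    chemical-image and color-image analysis tracks.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    tiff,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    signal,
    mixOmics,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
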