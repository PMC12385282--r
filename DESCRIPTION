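Package: specres
Title: Hyperspectral Unmixing and Gaussian Process Quantification of
    Surface Pesticide Residues
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for short-wave infrared (SWIR) hyperspectral
    images of leaf surfaces carrying pesticide residues. Provides reflectance
    calibration against white/dark references, ENVI (BIL) and plain-text cube
    input/output, multivariate curve resolution by alternating least squares
    (MCR-ALS) with non-negativity constraints and SIMPLISMA or
    reference-spectrum initialization, abundance-map-guided spectral
    extraction, Gaussian process regression of residue concentration with
    kernel selection by nested cross-validation, partial least squares and
    support vector regression baselines, ICH-style limit-of-detection
    estimation, Mann-Whitney comparisons of abundance distributions, and a
    synthetic scene/concentration-series generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    Rcpp,
    e1071,
    mixOmics,
    yaml,
    jsonlite,
    rlang
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    kernlab
Config/testthat/edition: 3
RoxygenNote: 7.3.3
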