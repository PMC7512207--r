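Package: eegdx
Title: Spectral and Nonlinear EEG Feature Pipelines for Dementia Screening
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of resting-state EEG for three-class
    discrimination of Alzheimer's disease, mild cognitive impairment and
    healthy controls. Provides a synthetic three-group cohort generator,
    band-pass/notch preprocessing and epoch segmentation, spectral features
    (relative band power, median frequency, individual alpha frequency,
    spectral entropy), nonlinear features (Lempel-Ziv complexity, central
    tendency measure, sample entropy, fuzzy entropy, auto-mutual
    information), fast correlation-based filter feature selection, LDA/QDA
    and multi-layer perceptron classifiers with subject-level majority
    voting, and the full evaluation stack (confusion matrices, Cohen's
    kappa, one-vs-all diagnostic metrics).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
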