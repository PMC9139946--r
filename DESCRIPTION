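Package: cspeeg
Title: Common Spatial Pattern Analysis and Classification of Multichannel EEG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for two-class classification of multichannel resting-state
    EEG recordings with common spatial pattern (CSP) spatial filtering.
    Provides band-pass preprocessing and non-overlapping segmentation, CSP
    fitting by simultaneous diagonalization of class covariance matrices,
    eight segment-level feature functionals (variance, band power, energy,
    and threshold, norm, sure, log-energy and Shannon entropies), several
    standard classifiers evaluated under stratified k-fold cross-validation
    with sensitivity, specificity, F-score and ROC/AUC, parameter sweep
    drivers over frequency band, CSP reduction number and segment length, a
    synthetic source-mixing EEG generator for validation, and readers for
    plain matrix, EDF and BDF recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    MASS,
    class,
    randomForest,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
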