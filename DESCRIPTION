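Package: rtmseeg
Title: Predicting rTMS Treatment Response from Resting-State EEG Band-Power Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for predicting whether Alzheimer's patients respond
    to repetitive transcranial magnetic stimulation (rTMS) from resting-state EEG.
    Implements windowed band-power feature extraction (delta/theta/alpha/beta/gamma),
    several feature-selection routes (PCA, Daubechies-4 wavelet coefficient selection,
    stepwise linear discriminant analysis, linear-SVM weight ranking, band
    restriction), RBF-kernel SVM and SWLDA classifiers, a balanced Monte-Carlo
    leave-one-out validation engine for small unbalanced cohorts, an
    interval-shrinking hyperparameter search, and a synthetic multichannel EEG
    generator with class-dependent band effects for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    signal
Config/testthat/edition: 3
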