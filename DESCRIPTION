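Package: doaindex
Title: Combined EEG/AEP Depth-of-Anesthesia Index Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and evaluates machine-learning indices of (un)consciousness
    under general anesthesia from spontaneous EEG and mid-latency auditory
    evoked potentials (AEP). Provides a synthetic cohort generator emulating a
    loss/return-of-consciousness transition protocol, automatic artifact
    rejection, seven spectral and complexity EEG parameters (weighted spectral
    median frequency, spectral entropy, Hurst exponent, approximate entropy,
    Lempel-Ziv complexity, permutation entropy and a median-frequency
    quotient), wavelet-derived AEP parameters, information-gain feature
    ranking, a uniform harness over SVM, Bayesian, logistic, neural-network
    and tree classifiers, and prediction-probability (PK) evaluation with
    patient-wise leave-one-out cross-validation and bootstrap confidence
    intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    e1071,
    nnet,
    rpart,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
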