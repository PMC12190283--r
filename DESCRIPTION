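Package: mfeeg
Title: Multiscale Fuzzy Entropy and Amplitude Transformations for EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Pipeline for assessing how amplitude transformations of
    multichannel EEG affect Multiscale Fuzzy Entropy (MFE) as a
    complexity biomarker for Alzheimer's disease. Provides a seeded
    synthetic cohort generator with multi-site gain heterogeneity,
    EDF and plain-matrix signal input/output, polyphase resampling and
    FIR band-pass preprocessing, five amplitude-transform conditions
    (reference, single/global min-max normalization, single/global
    standardization), a fuzzy-entropy kernel with coarse-graining over
    scale factors, long-scale feature extraction,
    leave-one-subject-out grid-search classification (SVM, random
    forest, k-nearest neighbours) with accuracy, expanded uncertainty
    and Matthews correlation coefficient reporting, and a statistical
    evaluation layer (FDR-corrected t-test grids, Cohen's d, mixed
    ANOVA, paired accuracy tests, inter-channel correlation
    preservation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    e1071,
    ranger,
    car,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
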