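Package: voxpath
Title: Voice Pathology Screening from Sustained Vowels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A pipeline for screening laryngeal pathology from sustained
    /a:/ vowel recordings. Provides a formant-filtered glottal-pulse
    simulator with ground-truth cycle perturbation, PRAAT-style acoustic
    features (fundamental frequency statistics, harmonics-to-noise ratio,
    five jitter and six shimmer variants), MFCC and STFT time-frequency
    images with patch crop augmentation, six classifier families (support
    vector machine, two gradient-boosted tree variants, a feed-forward
    network, and one- and two-dimensional convolutional networks on raw
    audio and spectral patches), and stratified five-fold evaluation with
    diagnostic metrics, ROC/AUC, and exact binomial confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    e1071,
    xgboost,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
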