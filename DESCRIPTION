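Package: fecgsqa
Title: Unsupervised Multi-Level Signal Quality Assessment for Non-Invasive Fetal ECG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing the quality of non-invasive fetal
    electrocardiogram (FECG) recordings without quality-annotated training
    data. Recordings are normalized, band-pass filtered, despiked and cut
    into 3 s segments; each segment is summarized by twelve quality
    features (approximate, sample, spectral and permutation entropy,
    detrended fluctuation analysis, Katz and Higuchi fractal dimensions,
    kurtosis, skewness, the pSQI and basSQI spectral quality indices, and
    the reconstruction error of a fully convolutional spectrogram
    autoencoder trained on high-quality segments only). Features are
    ranked by unsupervised multi-cluster feature selection (MCFS) and the
    top-ranked features feed a self-organizing-map classifier that assigns
    high, medium or low quality to each segment. Evaluation utilities
    quantify how removing detected low-quality segments reduces fetal
    heart-rate estimation error. A synthetic abdominal-FECG generator
    provides labeled data for testing the whole pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    grDevices,
    jsonlite,
    png,
    pracma,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
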