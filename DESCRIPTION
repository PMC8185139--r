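Package: gazegraph
Title: Multimodal EEG and Eye-Tracking Classification with Feature-Graph
    Convolutional Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Joint analysis of resting-state EEG and eye-tracking fixation
    logs for two-group classification studies (e.g. autism spectrum disorder
    screening cohorts). Multi-domain EEG features (approximate, sample,
    permutation, wavelet and short-time-Fourier spectral entropies, mean
    amplitude, Pearson-correlation channel synchronization) and per-test
    area-of-interest fixation durations are fused as the nodes of a
    covariance-thresholded feature graph and classified with a two-layer
    graph convolutional network over a block-diagonal batch adjacency.
    Includes a seeded synthetic two-group cohort generator so the whole
    pipeline is testable without access to clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Matrix,
    randomForest,
    Rcpp,
    signal,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
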