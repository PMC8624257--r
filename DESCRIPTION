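Package: semgshift
Title: Electrode-Shift-Robust Feature Selection and Hand-Posture
    Classification for Armband Surface EMG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for studying how electrode shift between wearing sessions
    of an 8-channel armband surface-electromyography (sEMG) sensor affects
    hand-posture recognition. Provides a parametric generator of
    multi-subject, multi-session synthetic armband recordings with a
    circular electrode-shift model; band-pass filtering and sliding-window
    segmentation; 21 classic time-domain feature extractors (including
    threshold-based features with an R x resting-RMS threshold rule and
    autoregressive/cepstral coefficients) plus the Hudgins and Du feature
    combinations; inter-session and inter-feature Pearson-correlation
    statistics for shift-robust feature selection; a small multilayer
    perceptron classifier evaluated under a sessions-of-training protocol
    and k-fold cross-validation; and experiment drivers for threshold,
    model-order, training-session, and posture-group sweeps with
    nonparametric comparison of accuracy distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    nnet,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
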