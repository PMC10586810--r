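Package: scenedecode
Title: Time-Resolved Decoding and Distance-to-Hyperplane Analysis of
    Multichannel Brain Recordings
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for linking time-resolved multichannel brain recordings
    (EEG/MEG-style epoched data) to categorization behavior. Implements
    multivariate noise normalization and pseudotrial-based time-resolved
    decoding with a linear support vector machine, the distance-to-hyperplane
    brain-behavior statistic (rank correlation of per-stimulus classifier
    decision values with reaction times), channel-space searchlight maps,
    representational similarity analysis with noise ceilings, extraction of
    reaction times from staged classifier probability trajectories via
    Shannon-entropy thresholds with leave-one-participant-out threshold
    selection, and nonparametric group statistics (sign-permutation tests,
    Benjamini-Hochberg false discovery rate control, bootstrap confidence
    intervals for peak latencies). Includes a synthetic-data generator with
    planted ground truth so every stage can be validated by parameter
    recovery without access to recording hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, tools, jsonlite, yaml, Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), e1071, withr, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
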