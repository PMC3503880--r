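Package: smrdetect
Title: Bedside EEG Detection of Covert Command-Following from
    Sensorimotor Rhythms
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to assess covert command-following from a minimal
    (four-electrode) bedside EEG recording of attempted hand movements.
    Simulates task-structured sensorimotor EEG with controllable
    event-related desynchronization/synchronization (ERD/ERS) ground
    truth, preprocesses continuous recordings (zero-phase least-squares
    FIR filtering, rational resampling, epoching, automated artifact
    rejection, bipolar derivation), detects average-level spectral
    modulations with cluster-based permutation statistics on
    time-frequency maps, and classifies single trials from sliding-window
    log bandpower with a cross-validated Gaussian naive Bayes classifier
    and a familywise max-statistic randomization test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
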