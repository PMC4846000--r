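Package: gaitatt
Title: Decoding Gait Attentional Demands from EEG Band-Power Features
Version: 0.1.0
Authors@R: person("gaitatt", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for multi-class decoding of the attention paid
    to gait from 32-channel treadmill-walking EEG. Implements a synthetic
    session generator (gait-locked motion artifacts, line noise, blinks,
    alternating motor alpha, per-task occipito-parietal gamma modulation),
    zero-phase band-pass and notch filtering, amplitude-based bad-channel
    detection with neighbor-mean reconstruction, maximum-visual-threshold
    signal standardization, Burg maximum-entropy spectra with six-band power
    features, Bhattacharyya-distance frequency-band selection, five-classifier
    run-wise 8-fold cross-validation, and finite-sample chance-level
    confidence ranges with rank-sum significance testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    MASS,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
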