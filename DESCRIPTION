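Package: gammaSE
Title: Gamma-Band Spectral Entropy Analysis of Two-Group Visual ERP Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for discriminating two groups of subjects (alcoholic
    versus control) from multichannel visual event-related potential (ERP)
    recordings. Epochs are band-pass filtered to the gamma sub-band
    (30-55 Hz) with a zero-phase elliptic filter, each channel is summarised
    by its normalized spectral entropy, channels are ranked by a Welch
    two-sample t-test on the group entropy distributions, the ranked (or
    native-order) channel subset is reduced by principal component analysis,
    and groups are classified with a k-nearest-neighbour classifier under
    stratified holdout validation. Includes readers and writers for epoch
    and feature tables, a permissive parser for the public alcoholism EEG
    trial-file layout, and a seeded synthetic-epoch generator with planted
    gamma-band complexity differences for calibrated end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
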