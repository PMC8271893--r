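Package: erpsign
Title: Event-Related Potential Analysis of Traffic-Sign Recognition in a
    Go/Nogo Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses stimulus-locked EEG epochs from a
    traffic-sign Go/Nogo recognition task in elderly and young drivers.
    Provides a synthetic generator for behavioral trial logs and ERP epochs,
    four preprocessing variants (epoch averaging, 20 ms moving-average
    smoothing, 4-30 Hz zero-phase band-pass filtering, and their combination),
    automated N200/P300/N400/P600 latency detection with a fixed-gap-time
    fallback anchored on N200, behavioral and latency summary statistics,
    and two correctness classifiers: a univariate Gaussian-mixture model
    fitted by expectation-maximisation and scored by log-likelihood
    difference, and a small 70-20-10-1 multilayer perceptron evaluated by
    stratified 4-fold cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
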