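Package: hazardTRF
Title: Forward-Encoding Models of Temporal Hazard in EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to test whether multichannel EEG tracks temporal hazard,
    the instantaneous conditional probability of an awaited event. Builds
    hazard-function regressors from discrete foreperiod distributions,
    estimates temporal response functions (TRFs) by lagged ridge regression
    on single trials, predicts held-out EEG by leave-one-out cross-validation,
    scores condition discrimination with a bounded correlation index, and
    assesses it with a cluster-based permutation test across electrodes.
    Includes a synthetic-EEG generator (known ground-truth TRFs convolved
    with hazard regressors plus 1/f coloured noise) so the full pipeline is
    testable with known ground truth, plus a noise-only control mirroring a
    resting-state null analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
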