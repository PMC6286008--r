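Package: regpoincare
Title: Lagged Poincare-Plot Analysis of Rheoencephalographic Pulse Signals
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for nonlinear characterization of
    rheoencephalographic (REG) cerebral blood-flow signals with lagged
    Poincare plots. Provides a synthetic REG generator with distinct
    apnea and baseline regimes, Chebyshev type II zero-phase band
    limiting and artifact screening, pulse-wave geometry features,
    the Poincare descriptors SD1, SD2, SDarea, SDratio, the lag
    correlation R and the Complex Correlation Measure (CCM), classical
    embedding-lag selection criteria (ACF and auto-mutual information
    based) plus a CCM-inflection criterion, normality-gated group
    statistics with ROC analysis, and Relief feature weighting with
    leave-one-out validated classifiers for apnea detection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    pracma,
    e1071,
    rpart,
    nortest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
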