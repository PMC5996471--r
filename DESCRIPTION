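Package: eegchaos
Title: Chaotic Analysis of EEG Epochs via Delay Embedding
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Nonlinear time-series analysis of fixed-length EEG epochs for
    studying loss of dynamical complexity in metabolic encephalopathy.
    Implements Takens delay embedding with autocorrelation, mutual-information
    and false-nearest-neighbour embedding-parameter estimators;
    Grassberger-Procaccia correlation dimension from the correlation-sum
    scaling region; and the largest Lyapunov exponent by the Rosenstein
    nearest-neighbour divergence method. Includes plain-text epoch I/O with
    zero-phase band-pass preprocessing, generators for canonical chaotic
    systems and synthetic EEG cohorts (broadband high-complexity signals
    versus low-complexity triphasic-wave signals), nonparametric group
    comparison with ROC cut-off analysis, support-vector-machine
    classification of epochs from the chaotic features, and a reproducible
    end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    signal,
    e1071,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
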