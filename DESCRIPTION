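Package: llpspeller
Title: Unsupervised Decoding of ERP Spellers by Learning from Label Proportions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the mean-map learning-from-label-proportions (LLP)
    decoder for event-related-potential (ERP) brain-computer interfaces,
    together with the two-sequence visual speller stimulus paradigm that makes
    label proportions available, shrinkage-regularized linear discriminant
    classification, signal preprocessing and interval-mean feature extraction,
    a synthetic ERP data generator, and evaluation procedures (online spelling
    simulation with per-character retraining, post-hoc re-analysis,
    mixing-matrix learning curves, and a leave-one-out homogeneity bootstrap).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
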