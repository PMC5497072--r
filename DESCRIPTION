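Package: chqclass
Title: Topic Classification of Chinese Consumer Health Questions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying free-text health questions posted online by
    Chinese-speaking consumers into six primary topics (diagnosis, treatment,
    condition management, epidemiology, healthy lifestyle, health provider
    choice). Implements question extraction from templated messages, a
    hierarchical topic-code model with liberal-match inter-annotator agreement
    (kappa), dictionary-based Chinese word segmentation and POS tagging behind
    a pluggable interface, seventeen lexical/grammatical/semantic/statistical
    feature families, Phi-score (F-score) feature selection with per-type
    average thresholds, balanced one-vs-rest classification with
    under-sampling and 10-fold cross-validation, precision/recall/F1
    reporting, and a template-based synthetic corpus generator for offline
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Matrix,
    e1071,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
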