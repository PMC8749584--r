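Package: edtriage
Title: Dual-Branch Neural Text Models for Emergency Department Triage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts hospital admission (or ICU admission or mortality) from
    structured emergency-department visit records by first rendering each
    record as a natural-language sentence and then classifying the sentence
    with a dual-branch neural model: a bidirectional GRU encoder with stacked
    feed-forward attention pooling for long-range structure, and a pyramid
    convolutional encoder with multi-kernel attention for local phrase
    structure. The two branches are fused by concatenating their 64-unit
    penultimate layers under a fresh softmax head and fine-tuning. Includes a
    declarative feature-schema reader, deterministic data-to-text
    serialization with an exact inverse parser, a synthetic emergency-visit
    cohort generator with a planted logistic outcome model and a known
    Bayes-optimal score, the full stratified train/validation/test protocol
    with repeated model selection, and a six-metric evaluation suite
    (sensitivity, specificity, precision, F1, accuracy, AUROC).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    yaml,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
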