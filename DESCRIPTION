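Package: dualsyn
Title: Dual-Feature Fusion Networks for Drug Combination Synergy Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts whether a drug pair acts synergistically or
    antagonistically in a given cancer cell line. Drugs are represented by
    SMILES strings, encoded with a small transformer fine-tuned by a
    contrastive (SimCSE-style) objective that uses dropout as the only
    augmentation, and by hashed atom-pair fingerprints; cell lines are
    represented by gene-expression vectors. All inputs are projected to a
    shared dimension and fused by two parallel paths, vector-level
    multi-head attention with a projected residual and a bit-level highway
    network, whose sum feeds a LayerNorm/linear/sigmoid prediction head
    trained with a regularized-dropout (R-drop) objective. Includes
    stratified and leave-one-drug-pair/drug/cell-line-out cross-validation
    with leakage audits, a nine-metric evaluation suite, and a seeded
    synthetic-data generator with a planted, learnable synergy rule.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    ChemmineR,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
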