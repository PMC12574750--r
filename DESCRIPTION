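Package: psymtl
Title: Multimodal Multitask Learning for Joint Depression Severity and
    Suicide Risk Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a multimodal multitask learning framework for the
    joint classification of depression severity (three ordinal levels from
    HAMD-17 scores) and suicide risk (binary, from SAD PERSONS scores) from
    pretrained audio and text embeddings. Provides early fusion by
    concatenation, a hard-parameter-sharing fully connected encoder with
    task-specific softmax heads, a homoscedastic-uncertainty weighted
    composite loss with learnable per-task variances, an AdamW trainer with
    linear warmup/decay and early stopping, stratified k-fold
    cross-validation with macro-averaged multiclass AUC, a synthetic cohort
    generator with correlated ordinal/binary labels and class-informative
    embeddings, and demographic group-comparison statistics for cohort
    tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
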