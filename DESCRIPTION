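Package: lnmil
Title: Attention-Based Multiple Instance Learning for Lymph Node
    Metastasis Prediction from Whole-Slide Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale, fully reproducible pipeline for weakly
    supervised whole-slide-image classification of lymph node metastasis
    (LNM) in T1 colorectal cancer. Provides a synthetic cohort and slide
    generator with planted evidence textures, tissue detection and patch
    tiling, a convolutional patch feature extractor with an attention
    pooling module and bag-level classifier trained end to end, patient
    level train/test "versions" with stratified five-fold
    cross-validation and ensemble prediction, ROC/AUC evaluation with
    Youden cutoff selection, clinical-utility panels against an
    all-positive surgery guideline baseline, McNemar paired comparison, a
    random-forest clinicopathologic baseline, and attention heatmap
    visualization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    png,
    withr,
    randomForest,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
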