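Package: tonguedx
Title: Tongue-Image Feature Extraction and GA-SVM Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A reusable pipeline for computerized tongue inspection: separates
    the tongue body from the tongue coating by a division-merging segmentation
    combined with a chrominance threshold, extracts per-region color features
    (RGB means with HSI and CIELAB transforms) and gray-level-difference
    texture statistics (contrast, angular second moment, entropy, mean),
    balances classes with SMOTE, scales features to [-1, 1], reduces dimension
    by PCA at a configurable retained-variance level, and trains an RBF-kernel
    support vector machine whose penalty and kernel-width parameters are
    selected by a genetic algorithm with cross-validated accuracy as fitness.
    Includes a synthetic tongue-image generator with ground-truth masks so the
    whole pipeline is testable without clinical data, and an evaluation module
    (stratified splits, confusion metrics, ROC/AUC, k-NN, naive Bayes and
    neural-network baselines).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    e1071,
    nnet,
    class,
    png,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
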