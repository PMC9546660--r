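Package: oralcad
Title: Computer-Aided Diagnosis of Oral Histopathology Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for two-class (normal oral epithelium versus oral
    squamous cell carcinoma) classification of stained histopathology images.
    Implements Reinhard colour-transfer stain normalization in the decorrelated
    l-alpha-beta space with per-channel density diagnostics, deep-feature
    extraction through a pluggable backbone contract (including a deterministic
    stub extractor for fully reproducible testing), binary particle swarm
    optimization wrapper feature selection driven by a k-nearest-neighbour
    error-rate fitness, and classifier training and evaluation (XGBoost, random
    forest, neural network) with confusion-matrix metrics and a multi-run
    comparison protocol. A synthetic-data module generates stained-tissue-like
    images and feature matrices with planted structure so that every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    class,
    stats,
    utils,
    jsonlite,
    yaml,
    xgboost,
    randomForest,
    nnet
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
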