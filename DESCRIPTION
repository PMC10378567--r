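Package: fusioncad
Title: Breast Lesion CAD by Hybrid Handcrafted and Deep Feature Fusion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: End-to-end computer-aided diagnosis pipeline for breast lesion
    images (ultrasound and mammography patches). Segments a lesion region of
    interest by histogram equalization, median filtering, Otsu thresholding
    and Suzuki-Abe border following; extracts local binary pattern and
    histogram-of-oriented-gradients texture descriptors with PCA reduction,
    BI-RADS-motivated shape features, and pluggable deep features; selects
    features with a genetic-algorithm wrapper and a k-nearest-neighbour
    mutual-information filter; balances classes by random undersampling; and
    classifies lesions with AdaBoost, gradient-boosted trees or a multilayer
    perceptron, reporting imbalance-aware metrics including the Index
    Balanced Accuracy. A seeded synthetic lesion generator makes every stage
    testable without external imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    png,
    rpart,
    nnet,
    xgboost,
    jsonlite,
    EBImage,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
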