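Package: thermostage
Title: Automatic Cellulite Stage Recognition from Infrared Thermograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A fully automatic pipeline for grading cellulite severity
    (Nuernberger-Mueller stages 0-3) from false-color infrared thermograms of
    the posterior thighs. Implements Sobel-based automatic region-of-interest
    extraction (contrast stretch, edge detection, annotation removal, noise
    removal, crop and resize to a 210x240 grayscale patch), histogram-of-
    oriented-gradients texture features alongside five simpler extractors
    (statistical moments, contour shape, local binary patterns, PCA
    projections, Euclidean distances to class templates), one-vs-rest
    multiclass classification with a three-layer feed-forward neural network
    and eight alternative classifier families, stratified 70/30 evaluation
    with per-stage sensitivity/specificity/F-score/ROC/AUC reports, and a
    synthetic thermogram generator so that every stage of the pipeline is
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    png,
    tiff,
    jpeg,
    e1071,
    MASS,
    class,
    rpart,
    randomForest,
    glmnet,
    yaml,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
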