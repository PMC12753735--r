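Package: hemosmear
Title: Blood Cell Segmentation and Classification from Microscopic Smear Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A segmentation-first pipeline for peripheral blood smear
    microscopy: contrast-limited adaptive histogram equalization and affine
    augmentation for preprocessing, a U-Net encoder-decoder for semantic
    segmentation of blood cells, a marker-controlled compact watershed on the
    Euclidean distance transform to separate overlapping cells and extract
    single-cell regions of interest, and a lightweight convolutional network
    classifying cells into nine classes (erythrocyte, erythroblast,
    neutrophil, basophil, eosinophil, lymphocyte, monocyte, immature
    granulocyte, platelet) under stratified 5-fold cross-validation.
    Includes a seedable synthetic smear generator with ground-truth instance
    maps, pixel- and object-level evaluation metrics (accuracy, precision,
    recall, F1, IoU, Dice, ROC/AUC), and Grad-CAM heatmaps. Networks are
    trained with a compact CNN engine written in C++ (He initialization,
    Adam, early stopping, learning-rate reduction on plateau).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    png,
    tiff,
    yaml,
    jsonlite,
    tools,
    utils,
    stats,
    grDevices,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
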