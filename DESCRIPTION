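Package: thyrotex
Title: First-Order Texture Analysis of Thyroid CT Regions of Interest
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A computer-aided detection toolkit for distinguishing thyroid
    nodules from normal thyroid tissue on non-enhanced CT slices. Reads
    single-frame CT DICOM images with paired binary region-of-interest masks,
    converts stored values to Hounsfield units, applies a 3x3 denoising filter
    bank (average, median, adaptive Wiener), and computes first-order texture
    statistics (entropy, uniformity, mean intensity, standard deviation,
    kurtosis, skewness) together with a 13-feature gray-level co-occurrence
    matrix baseline over each masked region. Features are min-max normalized,
    screened by two-sample t-tests, optimized by sequential floating forward
    selection with a k-nearest-neighbour leave-one-out criterion, and
    classified by an RBF-kernel support vector machine (with grid-searched
    hyperparameters), linear discriminant analysis, or a one-hidden-layer
    neural network. Confusion-matrix indices and ROC/AUC complete the
    evaluation. A seeded synthetic phantom generator emulating homogeneous
    normal thyroid versus heterogeneous nodules (cysts, calcifications,
    photon noise) makes the whole pipeline testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    e1071,
    MASS,
    png,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    yaml
Config/testthat/edition: 3
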