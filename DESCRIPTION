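Package: mammocad
Title: Microcalcification Detection and Classification in Digital Mammograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A computer-aided detection (CAD) pipeline for microcalcification
    (MC) clusters in digital mammograms: DICOM-to-PNG preprocessing with
    patient metadata extraction, rotation-based dataset augmentation,
    grayscale channel conversion, morphological MC candidate detection with a
    physical diameter filter, and benign/malignant classification with a
    fully connected depthwise-separable convolutional neural network
    (FC-DSCNN) next to a standard-convolution baseline (DCNN). The
    convolutional engine (depthwise-separable and standard convolution,
    batch normalisation, max-pooling, dense/softmax layers, AdaGrad training
    with sparse categorical cross-entropy) is implemented from first
    principles in R and C++. A synthetic phantom generator renders
    breast-like backgrounds with bright spots of 0.1-0.7 mm diameter in four
    spatial-distribution archetypes (clustered, segmental, regional,
    diffuse), so the whole pipeline is exercisable end-to-end without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
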