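Package: lucad
Title: Lung Nodule Detection and Benign/Malign Classification on CT Slices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A four-stage computer-aided detection (CAD) pipeline for lung
    nodules on single-slice chest CT images: image enhancement (median
    denoising, Laplacian sharpening, histogram equalization), lung volume
    extraction by dual-threshold masking with border clearing and binary
    morphology (LUVEM) plus an Otsu baseline and Jaccard/Dice overlap
    metrics, candidate nodule detection by a gradient circular Hough
    transform over three radius bands, nodule segmentation with a
    per-region self-organizing map, a 123-element feature vector
    (first-order statistics, shape descriptors, Haralick co-occurrence
    texture at four angles, wavelet subband energies), PCA reduction with
    a class-size component rule, and a probabilistic neural network
    classifier evaluated by leave-one-out cross-validation, confusion
    matrices, size-stratified performance criteria and ROC/AUC.  A seeded
    synthetic chest phantom generator provides ground-truth lung fields,
    vessels and benign/malign nodules for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    png,
    jsonlite,
    yaml,
    Rcpp,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
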