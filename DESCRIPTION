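Package: radpath
Title: Multimodal Histopathology and MRI Radiomics Prediction of Glioma IDH1 Status
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An automated machine-learning pipeline that integrates whole-slide
    histopathology image features with multi-sequence MRI radiomics to predict
    IDH1 mutation status in diffuse glioma. Provides automated region-of-interest
    selection on H&E tiles (watershed nuclei detection for the highest-cell-density
    tile, HSV-histogram representative tiles), a 22-feature nuclear morphometry
    bank and a 171-feature intensity/co-occurrence bank for histology, a
    1,132-feature 3D radiomics bank (first-order, shape, GLCM, GLRLM, GLSZM, GLDM
    over original, Laplacian-of-Gaussian and wavelet-filtered volumes), random-forest
    recursive feature elimination nested in stratified 10-fold cross-validation,
    and local surrogate (LIME-style) explanations of individual predictions.
    Synthetic H&E tiles and ellipsoidal MR phantoms with known class effects make
    every stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    RNifti,
    ranger,
    pROC,
    jsonlite,
    png,
    yaml,
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
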