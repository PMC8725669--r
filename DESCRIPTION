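Package: sonoquant
Title: Quantization-Assisted Lesion Segmentation and Saliency Feature
    Fusion for Breast Ultrasound
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing B-mode breast ultrasound images with one
    hypoechoic lesion per image. Provides multilevel Otsu thresholding and
    quantization-based refinement of coarse lesion segmentations, bottom-up
    saliency features built from independent-component-analysis sparse
    filters with generalized Gaussian response models, serial (concatenation)
    feature fusion with a deterministic deep-feature stub, soft dice / focal
    / total segmentation losses and mean-IoU / mean-F evaluation, stratified
    k-fold cross-validation with pooled confusion matrices and the
    accuracy / precision / recall / F1 / Cohen's kappa metric set, a seeded
    speckle-phantom generator for benign (smooth oval) versus malignant
    (irregular) lesions, and an end-to-end pipeline orchestrator.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    EBImage,
    glmnet,
    e1071,
    rpart,
    jsonlite,
    png,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
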