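Package: iplfseg
Title: Imbalance-Aware Lesion Segmentation for Ultrasound Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for semantic segmentation of sparse hypoechoic lesions in
    ultrasound images under severe class imbalance. Implements the
    integrated-on-positive loss function (IPLF), an asymmetric training loss
    that amplifies gradients on ground-truth-positive pixels while bounding
    the penalty on background pixels, together with a dual-encoder U-Net-style
    segmentation network whose second encoder is a frozen classification-
    pretrained feature extractor. Includes confusion-count evaluation metrics
    (precision, recall, Dice, accuracy, specificity, balanced accuracy and a
    false-positive-ratio decomposition), PSNR-calibrated multiplicative
    speckle-noise injection, a synthetic ultrasound phantom generator with
    patient-level dataset splitting and augmentation, a compact CPU training
    stack (Adam, group normalisation, SeLU), and a command-line interface for
    reproducible desk-scale experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    graphics,
    Rcpp,
    EBImage,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
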