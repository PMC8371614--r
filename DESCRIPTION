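Package: vesselseg
Title: Retinal Vessel Segmentation with an SE-Gated Residual Recurrent U-Net
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pixel-level segmentation of blood vessels in fundus photographs
    using a compact U-shaped convolutional network whose encoder and decoder
    blocks combine squeeze-and-excitation channel gating, residual skips and
    recurrent convolution. Includes the full companion pipeline: green-channel
    intensity preprocessing (standardisation, min-max normalisation, gamma
    correction, CLAHE), random-patch training-set construction with rotation
    augmentation, Dice-loss training with L2 weight decay under Adam, and a
    pixel-classification evaluation suite (accuracy, sensitivity, specificity,
    precision, F1, mean IoU, ROC/AUC). A synthetic fundus-image generator with
    exact vessel ground truth makes the whole pipeline testable end-to-end
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    EBImage,
    png,
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    tiff,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
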