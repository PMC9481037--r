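Package: praseg
Title: Pyramid Residual Attention Networks for Skin-Lesion Segmentation
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds, trains and evaluates pyramid residual attention (PRA)
    convolutional modules and the three-level PRAN encoder-decoder network
    for binary segmentation of dermoscopic skin-lesion images. Includes the
    PRA sub-components (multi-scale convolution pyramid, squeeze-excitation
    style channel attention with summed average/max pooled descriptors,
    group-normalized residual unit), ablation variants, a PRA-bottleneck
    U-Net (PRAU), Dice loss, a pixel-wise segmentation metric suite
    (Dice, IoU, accuracy, specificity, sensitivity, PR/ROC curves), an
    ISIC-layout image/mask data pipeline with augmentation, and a seeded
    generator of synthetic dermoscopy-like image/mask pairs for CPU-scale
    experiments. All tensor operations (convolution, transposed convolution,
    pooling, group normalization) ship with hand-derived backward passes so
    networks are trainable on a plain CPU with Adam.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    EBImage,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
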