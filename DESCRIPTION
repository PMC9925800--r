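Package: camrel
Title: Reliability of Class Activation Maps for Soft-Boundary Tissue Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate how reliably class activation maps (CAMs) segment
    tissue regions whose boundaries are soft, i.e. not crisply defined at the
    pixel level. Provides a synthetic generator of grayscale image stacks in
    which two classes differ only by a smooth texture perturbation with known
    per-pixel ground truth and a coupled liquid-loss scalar; background masking,
    augmentation and leakage-free sample-level splitting; small trainable
    convolutional classifiers exposing activations and class-score gradients;
    five CAM methods (Grad-CAM, Grad-CAM++, Score-CAM, Faster Score-CAM,
    Layer-CAM) with shared binarization post-processing; and agreement
    statistics (IoU, mean IoU, cross-method and cross-model mean pairwise IoU,
    Spearman correlation against liquid loss, Kruskal-Wallis group tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    png,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
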