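Package: feedscan
Title: Recognition of Dairy Cow Feeding Behaviour from Instance Segmentation Masks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for recognizing the feeding behaviour of dairy cows at the
    feed fence from RGB video. Implements MSE/PSNR frame-redundancy sampling,
    COCO-dialect annotation handling with mosaic and horizontal-flip
    augmentation, an attention-augmented RefineMask-style instance-segmentation
    model (ResNet-50 backbone with convolutional block attention, feature
    pyramid neck with efficient channel attention, GIoU box regression, and a
    multi-stage mask branch with semantic fusion), COCO-style average-precision
    evaluation, and the mask-overlap logic that turns per-frame head and
    feed-pile segmentations into per-fence feeding states, feeding times, and
    mean-absolute-error timeline evaluation. A synthetic barn-scene generator
    provides fully ground-truthed images, clips and perturbed detection sets
    for testing every component without farm data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mgcv,
    withr
Config/testthat/edition: 3
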