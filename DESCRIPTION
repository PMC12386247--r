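Package: pestfuse
Title: Multimodal Pest and Predator Detection with Cross-Modal Attention and Environment-Guided Gating
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale reference implementation of a multimodal object-detection
    framework for field pest and natural-enemy monitoring. Paired RGB and thermal
    infrared images are encoded by shallow convolutional branches, fused by a
    cross-modal attention module that down-weights locally inconsistent regions via
    Kullback-Leibler divergence between activation histograms, and gated by an
    environment-guided modulation tensor derived from temperature, humidity and
    light-intensity time series through a state-space (SS1D) stack. Detection uses a
    DETR-style set-prediction head with decoupled pest and predator query sets,
    Hungarian matching, class-imbalance-weighted cross-entropy, L1 and generalized-IoU
    box losses and a pest/predator contrastive embedding loss. Includes a synthetic
    scene generator with COCO-style annotations and 1 Hz sensor streams, a pure-R
    reverse-mode automatic-differentiation engine used to train the model end-to-end
    on a CPU, and PASCAL-VOC-style precision/recall/F1/mAP@50 evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
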