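Package: airseg
Title: Interconnected Attention Blocks for 2D Airway Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements the AirSeg interconnected attention block for 2D
    airway segmentation: five attention operators (image, positional,
    semantic, self-channel and cross-spatial attention), each gated in
    parallel by a learnable variance-based embedding module, composed into
    a block that plugs into UNet-like encoders. Provides plain and residual
    UNet backbones with hand-derived backpropagation and an Adam optimiser,
    a hybrid Dice plus IoU training loss, per-image segmentation metrics,
    a synthetic branching-airway phantom generator for CPU-scale
    experiments, and a train/evaluate/ablate pipeline with an ablation
    harness over attention subsets, embedding variants and fusion modes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    png,
    RNifti,
    EBImage
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
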