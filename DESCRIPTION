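Package: pcsanet
Title: Parallel Channel-Spatial Attention Networks for Pest Image Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and trains convolutional image classifiers that fuse a
    parallel channel-spatial attention (PCSA) module into bottleneck residual
    blocks, for recognising small foreground objects (crop pests) on cluttered
    backgrounds. Provides the attention module itself (squeeze/excite channel
    gating, cross-channel spatial gating, and parallel fusion), a configurable
    residual backbone, an offline image-augmentation pipeline with
    leakage-free stratified train/validation splitting, stochastic gradient
    descent with momentum and a plateau learning-rate schedule, multi-class
    evaluation metrics, and a seeded synthetic-image generator so the full
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
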