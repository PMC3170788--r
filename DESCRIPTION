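Package: modfuse
Title: Medical Image Modality Classification by Equal-Contribution Kernel Fusion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies medical images into acquisition modalities (CT, MR,
    PET, ...) from multiple visual features and a caption-derived textual
    feature. Implements global histogram descriptors (gray, quantized color,
    block-based gradient-orientation edge, block-based local variance), a
    dense-SIFT bag-of-visual-words histogram over a k-means codebook, and a
    binary keyword histogram from image captions. Per-feature chi-square, L1
    or L2 distances are turned into RBF kernels normalized by each feature's
    mean training distance so every feature contributes on the same scale
    (joint kernel equal contribution), averaged into a fused kernel for a
    one-vs-one support vector machine, with a second-stage refinement step
    that re-classifies samples predicted into easily confused modality groups
    using group-local classifiers. Includes a deterministic synthetic
    image-plus-caption generator, cross-validation and fixed-split evaluation
    drivers, and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    kernlab,
    png,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
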