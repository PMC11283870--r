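Package: plantforge
Title: Exemplar-Based Synthetic Plant Image Generation and Leaf Posture Digitization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for phenotyping sapling-stage trees from RGB images. Builds a
    database of annotated plant components (leaf blades with midvein and petiole
    regions, trunks) from palette-coded annotation maps, composites them into
    synthetic plant scenes with pixel-exact instance annotations for training
    instance-segmentation models, converts losslessly between per-instance mask
    datasets and YOLO segmentation polygon files, digitizes leaf growth posture
    (horizontal petiole and midvein angles) from instance annotations by IoU
    matching and line fitting, and provides a multitask (variety x drought-stress
    level) classification scaffold with a fused cross-entropy loss. Includes a
    procedural fixture generator with known ground-truth geometry so the full
    pipeline is testable without photographs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
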