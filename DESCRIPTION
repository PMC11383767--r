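Package: resswin
Title: Residual Swin Transformer for Cotton Pest Damage Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Classifies cotton leaf pest damage (aphid, leaf mite, mirid) in
    complex-background field images with a hierarchical shifted-window
    transformer augmented by convolutional residual modules and per-stage
    skip connections. Ships the full pipeline: bicubic resizing with the
    Keys interpolation kernel, a six-transform augmentation set, manifest
    construction with per-class 7:2:1 splitting, a pure-R transformer
    implementation with hand-derived backpropagation (training via Adam),
    confusion-matrix metrics, Grad-CAM explanation, and a procedural
    generator of labeled synthetic leaf images for offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    png,
    jpeg,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
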