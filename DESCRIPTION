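Package: feedtray
Title: Lightweight Detection of Residual Shrimp Feed in Feeding-Tray Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating a lightweight detector of
    residual feed particles on shrimp feeding trays. Implements a
    parameter-free three-branch attention mechanism (global energy, local
    variance, edge response) in the SimAM family, an elongation- and
    orientation-aware Wise-IoU bounding-box regression loss, and
    re-parameterizable ghost-feature convolution blocks with exact
    train-to-inference fusion. Includes an exact architecture profiler
    (parameters, GFLOPs) for nano-scale detector layouts, a seeded synthetic
    feeding-tray scene generator with YOLO-format labels that emulates dense
    small-particle statistics, a pure-R trainable compact detector for
    desk-scale experiments, and standard detection metrics (precision,
    recall, mAP, confusion matrix).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    yaml,
    stats,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
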