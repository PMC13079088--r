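Package: holoflow
Title: In-Flow Holographic Detection and Enumeration of Circulating Tumor Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for in-flow digital holographic
    microscopy (DHM) detection of circulating tumor cells (CTCs). Provides a
    seeded physics-based generator of in-line Gabor hologram frame stacks with
    synchronized two-channel photomultiplier (PMT) fluorescence traces;
    streaming background subtraction and focus scoring; a compact
    multi-resolution keypoint-heatmap detector trained with an asymmetric
    binary cross-entropy loss, session-level hard-sample mining and
    pseudo-labeling; peak extraction, track linking and detection scoring;
    robust PMT pulse detection with cross-channel matching; and fusion,
    marker gating, per-millilitre enumeration and diagnostic-performance
    arithmetic (recovery, false-positive rate, positive predictive value,
    depletion and enrichment folds).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    tiff,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
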