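Package: gradchamber
Title: Gradient-Chamber Chemotaxis Assay Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative analysis of direct-viewing gradient-chamber
    chemotaxis assays in 3D collagen gels. Models the chemoattractant
    gradient by Fickian diffusion (semi-infinite-slab closed form and a
    conservative finite-difference solve of the three-section chamber),
    estimates the diffusion coefficient from concentration time series,
    calibrates fluorescence intensity against tracer concentration, and
    computes cell-trajectory motility statistics: cumulative chemotactic
    index, motile fraction, binned velocity components, per-cell pre- and
    post-stimulus speeds, and the t-test-based biased-cell fraction. A
    biased persistent random-walk generator coupled to the simulated
    gradient provides synthetic experiments with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pracma,
    ggplot2
Config/testthat/edition: 3
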