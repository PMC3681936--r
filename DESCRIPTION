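Package: axontrace
Title: Serial-Section Reconstruction and Morphometry of Myelinated Axons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for reconstructing myelinated axons from serial
    cross-section light-microscopy image stacks. Provides a synthetic nerve
    phantom generator with ground truth, rigid slice alignment and stack
    preprocessing, seeded region-growing ("wildfire") segmentation with
    slice-to-slice trace propagation and tracing-abortion quality control,
    per-axon morphometry with area-fluctuation normalization and class
    statistics, and conversion of traces into watertight triangle meshes with
    volume-preserving HC Laplacian smoothing, quadric edge-collapse
    decimation, overlap auditing and PLY/VRML export.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    png,
    tiff,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    grDevices,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
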