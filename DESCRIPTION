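Package: plateletPattern
Title: Quantification of Geometry-Guided Platelet Spreading on Striped
    Protein Micropatterns
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Single-platelet morphometry on striped protein micropatterns:
    parametric stripe-pattern geometry and rasterization, a stochastic
    simulator of filopodia-guided platelet spreading with a fluorescence
    renderer, segmentation of pattern and platelet channels, per-platelet
    metrics (on-pattern area fraction, stripe-axis aspect ratio,
    gap-spanning classification, filopodia lengths by skeleton geodesics,
    actin edge-enrichment ratio), and per-geometry aggregation with
    exponential trend fits. Includes a pipeline runner producing
    measurement tables, curves and plots from a single configuration file.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    EBImage,
    igraph,
    minpack.lm,
    yaml,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: CellBiology, SingleCell, Visualization, Software
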