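Package: aggscreen
Title: Quantitative Analysis of Chaperone Screens for Protein Aggregation Modulation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for flow-cytometry pulse-shape (PulSA) based screens of
    protein aggregation modulators. Implements viability/size/pulse-shape
    gating of aggregate-containing cells, the log2 Aggregation Modulation
    Score with its empirical control-replicate confidence bands, dose-response
    summaries, FRAP (fluorescence recovery after photobleaching) mobility
    analysis with binned median curves and FDR-corrected per-bin comparisons,
    deterministic microscopy quantification of aggregates (cell counting,
    watershed segmentation, nuclear versus extranuclear partition, neuron
    z-stack pipeline), and gene-set expression-shift and restoration
    statistics. Ships seeded synthetic-data generators with ground truth for
    every input type so the whole pipeline is testable without instrument
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    EBImage,
    jsonlite,
    yaml,
    tiff,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
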