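Package: polarityscreen
Title: High-Content RNAi Screen Analysis for T-Cell Polarity Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for image-based RNAi screens of
    integrin-induced T-cell polarization. Computes five cell-shape
    read-outs (1/(form factor), nuclear displacement, cell area,
    gyration radius and elongation factor) from paired cell/nucleus
    label masks, normalizes well-level profiles to per-plate
    non-targeting controls, standardizes them to plate Z-scores,
    calls hits with a replicate-consistency rule across triplicate
    screens, classifies phenotype direction, and clusters gene
    morphology profiles with average linkage and optimal leaf
    ordering. A seed-controlled generator produces synthetic plates
    (label-mask images or direct per-cell feature draws) with planted
    per-gene effects so every stage is testable without raw screen
    data. Also provides the live-cell track metrics (velocity, origin
    of distance, speed) used in validation assays.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    ape,
    jsonlite,
    tiff,
    yaml,
    pheatmap
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
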