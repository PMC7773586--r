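Package: cytokinetics
Title: Quantitative Kinetic Landscape of Cytokinesis from Time-Lapse Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Event-aligned quantification and comparison of protein
    accumulation kinetics at the yeast division site. Provides a
    ground-truth synthetic microscopy generator (per-cell intensity
    traces, biphasic actomyosin-ring constriction, rendered
    multi-channel movies), ROI-based intensity and ring-diameter
    quantification with spindle-breakage event detection, alignment of
    single-cell traces to the spindle-breakage clock, mean +/- SD
    kinetics, kinetic-signature extraction (multi-peak detection,
    arrival/departure times), two-segment changepoint fitting of ring
    constriction, condition comparisons, and Pearson-correlation
    similarity ranking with functional-module assignment.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    yaml,
    jsonlite,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'templates.R'
    'simulate.R'
    'render.R'
    'quantify.R'
    'align.R'
    'cytokinetics-package.R'
    'kinetics.R'
    'similarity.R'
    'io.R'
    'pipeline.R'
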