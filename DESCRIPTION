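Package: cerealmet
Title: Comparative Leaf Metabolomics of Cereal Crops with Rule-Based
    Glycoside Annotation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for LC-MS/MS untargeted and widely-targeted metabolomics
    of cereal leaf panels. Implements exact-mass and ion arithmetic over
    molecular formulas, MGF/MSP spectral input and output, feature-level
    quality control (blank-ratio, height, signal-to-noise and QC
    coefficient-of-variation filters, MS2 spectral tag library
    construction), a declarative rule-based annotation engine for
    benzoxazinoid and flavonoid glycosides built on neutral-loss
    decomposition and characteristic-fragment matching, presence/absence
    comparative analytics across species (shared, species-specific and
    species-missing metabolites, per-class detection proportions and their
    coefficient of variation), abundance analytics (log2 transform, row
    Z-scores, PCA, hierarchical clustering with class-composition tables
    and hypergeometric pathway enrichment), pathway graphs with
    mass-delta-based single-step reaction inference, and a synthetic-data
    generator that reproduces the statistical structure of a
    nine-species defense-metabolite panel.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    yaml,
    igraph,
    withr,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
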