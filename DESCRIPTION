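Package: woundmetab
Title: Untargeted Metabolomics Time-Course Analysis of Burn Wound Healing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing untargeted LC-MS feature tables from
    longitudinal burn wound healing studies. Implements quality-control
    based feature filtering and QC-anchored LOESS drift normalization,
    two-way ANOVA time/treatment scans with Benjamini-Hochberg control,
    per-day t-test/fold-change volcano classification, consensus
    hierarchical trajectory clustering with monotone-up (U), monotone-down
    (D) and peak (P) pattern labelling, accurate-mass adduct annotation
    with Schymanski-style confidence levels, and hypergeometric pathway
    over-representation with relative betweenness-centrality impact
    scores. A synthetic-study generator reproduces the porcine burn wound
    design (deep partial- and full-thickness wounds, five biopsy days,
    pooled QC injections) so that every stage of the pipeline can be
    exercised and validated without access to raw spectra.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    cluster,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
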