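Package: screjuv
Title: Single-Cell Analysis of Aging and Rejuvenation in Regenerative Animals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, simulation-backed pipeline for studying
    transcriptomic aging and its reversal by regeneration in single-cell
    RNA-seq data. Provides cell and gene quality control, library-size
    normalization and highly-variable-gene selection; an expression
    stochasticity statistic based on mean mutual distances between cell
    expression vectors, with closed-form Gaussian calibration; decomposition
    of cell-to-cell variability into technical and biological components;
    cell-type composition and cell-cycle phase analysis; age-associated gene
    calling by per-tissue Wilcoxon differential expression and quadrant-based
    rejuvenation-reversal scoring; and a comparative-signature stage built on
    pseudo-bulk aggregation, relative-log-expression normalization, per-gene
    log-log age models, signed-p gene ranking, and preranked permutation GSEA.
    A negative-binomial synthetic-data generator with planted ground truth
    (effect sizes, reversal fractions, proportion shifts, cell-cycle programs)
    makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    MASS,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    withr
Config/testthat/edition: 3
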