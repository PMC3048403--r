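Package: tristage
Title: Stagewise Differential Expression and Trajectory Analysis for
    Three-Stage Progression Models
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of expression microarray data from cell-culture
    models of neoplastic progression sampled at three stages (early,
    intermediate, late). Provides trimmed-mean array scaling, pairwise
    stage contrasts with fold-change and t-test filtering, classification
    of differentially expressed probes into expression-trajectory patterns
    (early, progressive, late), hypergeometric gene-set
    over-representation, cross-species concordance scoring against
    archived reference platforms via percentile ranks and a cumulative
    binomial overlap statistic, relative-quantification (delta-delta-Ct),
    densitometry and fluorescence-per-cell assay statistics, and a
    synthetic-data generator with known ground truth for end-to-end
    validation. Readers for tab-delimited expression tables, the GEO
    series-matrix dialect and GMT gene sets are included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    jsonlite
biocViews: GeneExpression, Microarray, DifferentialExpression,
    GeneSetEnrichment, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
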