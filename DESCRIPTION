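Package: coexAge
Title: Weighted Co-Expression Modules, Hub Genes and Age Trajectories in
    Two-Cohort Transcriptomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested re-implementation of a differential co-expression
    workflow for studying transcriptomic aging across two cohorts:
    soft-thresholded weighted gene co-expression network construction with
    topological overlap, module detection by hierarchical tree cutting,
    module eigengenes and module-trait correlation, differential expression
    screening with Benjamini-Hochberg control, maximal clique centrality
    hub ranking on protein-protein interaction subnetworks, hypergeometric
    over-representation analysis against user-supplied gene sets,
    piecewise-linear age-trajectory breakpoint detection, and cross-cohort
    shared-signature extraction. A synthetic two-cohort generator with
    known ground truth (planted age-correlated modules, a shared module,
    hub genes embedded in dense interaction neighborhoods) makes every
    stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    limma,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite,
    knitr,
    rmarkdown
biocViews: GeneExpression, Network, NetworkInference, GraphAndNetwork,
    DifferentialExpression, GeneSetEnrichment, Transcriptomics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
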