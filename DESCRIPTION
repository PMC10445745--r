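Package: eyefield
Title: Regulatory Dynamics of Eye-Field Specification from Time-Course
    RNA-seq and ATAC-seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to characterize a cell-state transition to the eye
    field from time-course bulk RNA-seq and ATAC-seq data, as generated
    from optic-vesicle organoid differentiation. Implements programme-gene
    gating (EF-up/EF-down/housekeeping sets), Gaussian-mixture trajectory
    clustering with consensus labels, consensus-peak construction and
    TAD-restricted peak-gene association, position-weight-matrix scanning
    with exact p-value computation, motif enrichment and a regularized
    logistic motif-importance model, expression-accessibility correlation,
    ATAC-seq footprinting metrics (footprint depth, flanking
    accessibility, occurrence-level footprint scores, differential
    binding), and candidate cis-regulatory-element prioritization with
    deletion-interval construction. Includes a synthetic-data generator
    that plants known regulators so every stage can be validated against
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    mclust,
    glmnet,
    jsonlite,
    limma,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
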