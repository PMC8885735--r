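Package: qpcrCoherence
Title: Reference Gene Validation for RT-qPCR via Model-Based Stability
    Selection and Coherence Scoring
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Selects and validates RT-qPCR reference genes by combining
    model-based (NormFinder-type) stability estimation with progressive
    removal of the least stable candidate gene, applied to an experimental
    model and all of its daughter models (sample subsets of size two or
    more). Target genes are relatively quantified against the per-model
    reference, compared between samples with pairwise tests (pooled t with
    Holm adjustment, Mann-Whitney, or Kruskal-Wallis with Dunn post hoc),
    and the consistency of significant expression differences across all
    models is summarised as a coherence score per target gene. Includes a
    seeded synthetic-data generator that emulates replicate-level qPCR
    tables with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: GeneExpression, qPCR, Normalization, Software
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'ModelSpace-class.R'
    'CoherenceAnalysis-class.R'
    'ExpressionTable-class.R'
    'coherence.R'
    'export.R'
    'normfinder.R'
    'qpcrCoherence-package.R'
    'quantify.R'
    'run-analysis.R'
    'stats-tests.R'
    'synthgen.R'
    'tables-io.R'
    'utils.R'
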