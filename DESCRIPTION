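Package: spatLCM
Title: Region-Resolved LCM Proteomics Analysis and Single-Cell Integration
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for laser-capture-microdissection (LCM)
    spatial proteomics of synovial tissue regions. Provides import of
    DIA protein-group abundance matrices, missingness filtering, log2
    transformation, median normalization, random-forest based iterative
    imputation, principal component QC, empirical-Bayes moderated
    differential expression with Benjamini-Hochberg control, one-vs-rest
    Cohen's d extraction of up-regulated region-specific protein markers,
    a z-score "Query" integration of region markers with a
    cluster-averaged scRNA-seq reference yielding region-by-cluster
    enrichment and depletion maps, preranked gene-set enrichment
    analysis, and a synthetic-data generator with planted ground truth
    for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    ranger,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    fgsea,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
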