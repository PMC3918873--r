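Package: betcore
Title: BET-Inhibition Core Transcriptional Program Analysis in AML
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable implementation of the analysis by which a
    BET/BRD4-dependent core transcriptional program is derived in acute
    myeloid leukemia: microarray preprocessing (detection-p filtering,
    variance-stabilizing transform, quantile normalization), empirical-Bayes
    moderated differential expression with FDR and fold-change gating,
    multi-cell-line signature intersection, ChIP-seq read filtering,
    extension and binned coverage, TSS-centered metaprofiles, a local-Poisson
    peak caller, super-enhancer calling from the ranked-signal inflection
    with 50 kb enhancer-to-gene assignment, and signature-driven hierarchical
    classification of a patient cohort with group-by-factor association
    tests. Ships seeded synthetic-data generators with recorded planted
    truth so the full pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    data.table,
    limma,
    mclust,
    IRanges,
    GenomicRanges,
    S4Vectors,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
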