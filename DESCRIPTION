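Package: clipfunnel
Title: Peak Calling, Target Scoring and Prioritization for iCLIP of an
    RNA-Binding Protein
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for individual-nucleotide resolution
    CLIP (iCLIP) of an RNA-binding protein, modelled on a CELF1 study in
    mouse lens. Aggregates cross-link events into scored sites, calls
    significant peaks by a permutation false discovery rate over small
    windows, merges peaks into scored binding clusters, computes per-gene
    CLIP scores restricted to 3'UTRs, retains ligand genes by a dual
    percentile rule, tests UGU motif enrichment, runs a GSEA-like
    running-sum enrichment of ligand sets in a signed-FDR-ranked
    differential-expression list, applies a multistep gene prioritization
    funnel, and provides reporter-assay statistics (sequential dual
    luciferase normalization, one-sample tests, paired morphometry). A
    synthetic-data generator with planted ground truth makes the whole
    pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
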