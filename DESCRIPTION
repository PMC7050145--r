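Package: mitocensus
Title: Consensus Mitochondrial-Targeting Prediction and Gene-Model
    Reconciliation for Compact Protist Genomes
Version: 0.1.0
Authors@R: person("mitocensus", "developers", role = c("aut", "cre"),
    email = "devel@mitocensus.org")
Description: Tools to infer a nucleus-encoded mitochondrial proteome from a
    compact nuclear genome: a consensus mitochondrial-targeting score built
    from external predictor tables, with binning, a candidate decision rule
    and curation overrides; splice-aware reconciliation of gene models
    against assembled transcripts (GT..AG intron calling, N-terminus
    assignment with an upstream-extension rule, SNP classification);
    genome-context statistics for co-assembled gene pairs; summary
    reporting; and a seeded synthetic-data generator so the whole pipeline
    runs and is verified without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    BiocGenerics,
    data.table,
    stringi,
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
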