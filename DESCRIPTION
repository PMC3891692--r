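Package: agemeth
Title: Aging Methylome Analysis for MeDIP-Seq with CpG Coupling
    Normalization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for methylated-DNA immunoprecipitation
    sequencing (MeDIP-seq) studies of age-related DNA methylation change.
    Ingests aligned paired-end fragments, applies proper-pair, mapping
    quality and duplicate filters, computes CpG enrichment and replicate
    correlation quality statistics, derives CpG-coupling-normalized
    methylation scores in 50 bp bins, calls differentially methylated
    regions (DMRs) between age groups with a conditioned negative binomial
    count test and Benjamini-Hochberg FDR control, tests for genomic DMR
    hotspots by permutation against the candidate-region background,
    quantifies genomic-feature enrichment of DMRs with Fisher's exact
    test, and associates DMRs with nearby genes. A synthetic-data module
    simulates a small genome, annotation and CpG-density-dependent MeDIP
    fragment sets with known ground truth so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
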