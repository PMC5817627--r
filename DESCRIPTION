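Package: dmrkit
Title: Differentially Methylated Regions from Bisulfite Sequencing Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-alignment analysis of CpG methylation from bisulfite
    sequencing (MethylC-seq/RRBS). Extracts per-CpG methylated and
    unmethylated counts directly from Bismark-style alignments, including
    novel CpG sites created by variants or indels, and merges the two
    strands of each CpG. Clusters CpG sites into regions with a modified
    single-linkage algorithm that splits oversized clusters at their
    largest internal gaps, then tests regions for differential methylation
    between two or more sample groups using a beta-binomial model with
    empirical-Bayes dispersion shrinkage, Wald tests, and
    Benjamini-Hochberg correction. Includes a seeded simulator for
    reference sequences, bisulfite reads, and beta-binomial count tables,
    and a command-line interface chaining the pipeline stages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    GenomicRanges,
    Rsamtools,
    rtracklayer,
    stats,
    utils
Suggests:
    igraph,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
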