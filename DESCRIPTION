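Package: bootreps
Title: Artificial Technical Replicates for RNA-Seq Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Generates artificial replicates of RNA-seq experiments by three
    strategies: bootstrapping sequencing reads from FASTQ files (FB),
    bootstrapping columns of the gene-by-sample count matrix (CB), and
    weighted mixing of samples (MO). Provides a self-contained
    negative-binomial Wald engine for differential expression (median-of-ratios
    size factors, gene-wise dispersion, Benjamini-Hochberg adjustment),
    hypergeometric over-representation analysis on GMT gene sets, and an
    evaluation layer that compares results across replicates via
    Spearman-distance Ward cluster trees, asymmetric overlap matrices,
    dispersion-distribution comparisons and selection-frequency stability
    reports. A synthetic-data generator (negative-binomial counts with paired
    technical replicates, toy transcriptome, read simulator and exact-match
    quantifier) makes the whole workflow testable end to end without external
    data or aligners.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings,
    ape
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
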