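Package: srnadekit
Title: Quality Checking, Normalization and Differential Expression for
    Small RNA Sequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A pipeline for bulk small RNA sequencing count data:
    collapsed-FASTA ingestion, exact short-read genome matching and
    GFF3-based annotation classification, replicate quality diagnostics
    (size-class and complexity profiles, positional nucleotide
    composition, MA values, top-N Jaccard indices, abundance windows),
    six normalization schemes including a rank-tie/zero-preserving
    quantile adaptation and subsampling to the minimum library size, a
    strand-bias Kullback-Leibler noise-offset estimator with LOESS
    smoothing, and a confidence-interval differential expression caller
    producing up/down/straight (U/D/S) expression patterns with log2
    offset fold changes. Includes a seeded synthetic-data generator with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    DESeq2,
    withr,
    optparse
Config/testthat/edition: 3
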