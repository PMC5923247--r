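Package: spliceHDP
Title: Nonparametric Bayesian Isoform Discovery and Quantification from
    Short-Read RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovers and quantifies mRNA isoforms across many RNA-seq
    samples without a reference transcriptome. Mapped short reads are
    summarised as read terms (start, end, covered-exon set) per gene; a
    hierarchical Dirichlet process admixture shares a global catalog of
    binary exon compositions across samples, and stochastic variational
    inference with merge-propose-reduce catalog moves fits per-sample
    isoform proportions. Includes transcript-level RPKM and ratio
    quantification, bipartite-matching precision/recall evaluation of
    inferred isoform sets, desk-scale read simulators (Dirichlet
    per-sample proportions with 5'-biased starts, and fragmentation of
    long reads into short reads), and group-specific splicing statistics
    (Dirichlet likelihood-ratio tests, population-specific allele
    enrichment).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    clue,
    GenomicRanges,
    IRanges,
    methods,
    Rsamtools,
    rtracklayer,
    S4Vectors,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
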