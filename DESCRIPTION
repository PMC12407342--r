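Package: kranzC4
Title: Cell-Type Expression, Subgenome Dominance and Cis-Regulatory
    Motif Profiling for Facultative C4 Photosynthesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Downstream analysis toolkit for single-nucleus expression and
    chromatin-accessibility studies of environmentally plastic C3-C4
    photosynthesis in allopolyploid sedges. Provides cell quality control
    and normalisation, per-cell-type expression profiling, a rank-sum
    differential-expression screen, the homeolog subgenome-dominance
    statistic (D-values and Weight_B/AB), accessible cis-regulatory
    motif-family frequency matrices with predominant and
    environment-triggered family calls, IUPAC consensus promoter scanning,
    reciprocal-best-hit orthology with a cross-species conserved-gene
    screen, and Ks-based divergence-time conversion. A synthetic-data
    generator with recorded ground truth emulates the study design
    (three growth conditions, mesophyll and Kranz cell types, A/B homeolog
    pairs) so every stage is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    SingleCellExperiment,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
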