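Package: triMark
Title: Multi-Mark ChIP-Seq Target-Gene Calling and Patient Cohort Scoring
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Implements a reusable pipeline that turns aligned ChIP-seq reads
    for multiple chromatin marks (e.g. MLL-N, AF4-C, H3K79Me2) into a
    consensus fusion-protein target-gene set, and scores such gene sets in
    patient expression cohorts. Includes clonal-read collapsing, fragment
    extension pileup, fold-over-background peak calling with an IP/input
    enrichment gate, strand-aware promoter and gene-body annotation windows,
    multi-mark target-gene rules and cross-cell-line consensus, gene-set
    expression scoring with two-sided Wilcoxon comparisons and log2 fold
    changes, minimal-residual-disease stratification, Kaplan-Meier and
    log-rank survival analysis, delta-CT qPCR quantification (ChIP percent
    of input and relative expression), and a deterministic synthetic-data
    generator with planted ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    survival,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: ChIPSeq, PeakDetection, GeneExpression, Survival, Software
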