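Package: paraloverlap
Title: Quantifying Target-Gene Overlap of Paralogous Transcription Factors
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to test whether two paralogous transcription factors regulate
    the same target genes from paired CRISPR knockout / CRISPR-activation
    perturbation RNA-seq. Implements a lightweight negative-binomial GLM with
    the combined (OE - ctrl-OE) - (KO - ctrl-KO) contrast that cancels
    CRISPR-system stress responses, a constrained bootstrap null for the
    expected Jaccard overlap of differentially expressed gene sets with basic
    bootstrap intervals, one-sample Z tests and observed/expected ratios,
    Fisher exact overlap tests, Wald Z-score correlation, an off-target
    candidate filter, and integration of TF binding peaks with target genes
    (TSS-window annotation, 1 Mb peak-gene linking, histone-mark filtering and
    a regulatory-potential based activating/repressive function test). A
    negative-binomial count simulator with ground-truth target annotations and
    synthetic peak/TSS fixtures makes the whole pipeline testable without
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    MASS,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
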