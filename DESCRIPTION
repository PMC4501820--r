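Package: mirna22q
Title: Small RNA-Seq Analysis of 22q11.2 Deletion iPSC-Derived Neurons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable reimplementation of a small RNA-seq
    analysis of induced-pluripotent-stem-cell-derived neurons carrying a
    hemizygous 22q11.2 deletion. Provides a synthetic-data generator that
    emulates the study design (negative-binomial mature-miRNA counts, a
    deletion interval halving in-region expression, isomiR end offsets,
    3' adapter ligation, sequencing errors and non-miRNA background reads);
    read-to-mature-miRNA quantification with adapter trimming, length
    filtering, one-mismatch hairpin mapping, end-offset assignment,
    genome cross-mapping resolution and read categorization;
    negative-binomial differential expression with median-of-ratios
    normalization, moderated method-of-moments dispersion, Wald tests and
    Benjamini-Hochberg correction; deletion-region Fisher enrichment;
    GO-term overlap-coefficient network construction with SIF/GraphML
    export; and qPCR delta-delta-Ct validation statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    rtracklayer,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    DESeq2,
    knitr,
    rmarkdown
Config/testthat/edition: 3
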