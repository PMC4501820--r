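#' Published differential-expression results for 22q11.2 deletion neurons
#'
#' The reported table of 45 differentially expressed mature miRNAs
#' (nominal p < 0.01 and fold change > 1.5) from the small-RNA-seq study
#' of 22q11.2-deletion iPSC-derived neurons that this package models
#' (GEO accession GSE65367): per-miRNA genomic coordinates, log2 fold
#' change (positive = lower in patients), raw and BH-adjusted p-values.
#' Used to validate the calling thresholds and the deletion-region
#' enrichment construction against the published counts.
#'
#' @return data.frame with columns `mirna`, `direction`, `coordinates`,
#'   `log2FC`, `pvalue`, `padj`, plus `contig`, `start`, `end` parsed from
#'   the first listed locus.
#' @export
reportedDeTable <- function() {
  path <- system.file("extdata", "de_mirnas_22q11_neurons.tsv",
                      package = "mirna22q", mustWork = TRUE)
  x <- read.table(path, sep = "\t", header = TRUE, quote = "",
                  stringsAsFactors = FALSE)
  names(x)[names(x) == "log2fc"] <- "log2FC"
  first <- sub(",.*$", "", x$coordinates)
  m <- regmatches(first, regexec("^([^:]+):([0-9]+)_([0-9]+)$", first))
  x$contig <- vapply(m, `[`, "", 2L)
  x$start <- as.numeric(vapply(m, `[`, "", 3L))
  x$end <- as.numeric(vapply(m, `[`, "", 4L))
  x
}

#' Cohort demographics of the modeled study
#'
#' The 12 subjects (6 controls, 6 patients carrying the 22q11.2 deletion)
#' whose iPSC lines produced the sequenced neuronal libraries, with age at
#' study, sex and diagnosis group.
#'
#' @return data.frame with columns `subject`, `age`, `sex`, `group`,
#'   `diagnosis`.
#' @export
cohortDemographics <- function() {
  path <- system.file("extdata", "cohort_22q11_demographics.tsv",
                      package = "mirna22q", mustWork = TRUE)
  read.table(path, sep = "\t", header = TRUE, quote = "",
             stringsAsFactors = FALSE)
}
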