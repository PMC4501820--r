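#' @import methods
#' @importFrom stats aggregate coef cor dhyper lm mad median p.adjust
#'   phyper pt rbinom reshape resid rlnorm rnbinom rnorm rpois runif sd
#'   setNames t.test var
#' @importFrom utils head read.table write.table
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom GenomicRanges GRanges seqnames start end strand width
#' @importFrom IRanges IRanges
#' @importFrom Biostrings DNAStringSet
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Simulation configuration for the synthetic 22q11.2 study
#'
#' Bundles every tunable of the synthetic-data generator: study design
#' (number of control and case libraries), the toy deletion interval, the
#' dosage effect applied to deletion-region miRNAs in case samples,
#' expression and dispersion of the negative-binomial count model, isomiR
#' end-offset probabilities, per-base sequencing error rate, the fraction of
#' non-miRNA background reads, the 3' adapter, and the RNG seed.
#'
#' @slot n_control,n_case Integer library counts per group (defaults 9 and 7,
#'   the design of the study being emulated).
#' @slot n_mirnas Number of hairpin genes in the toy reference.
#' @slot deletion_interval `GRanges` of length 1: the hemizygous deletion.
#' @slot deletion_effect Fold multiplier applied to deletion-region miRNA
#'   means in case samples (default 0.5, i.e. one remaining copy).
#' @slot extra_de Named numeric vector of additional per-mature fold effects
#'   (names are mature ids; may be empty).
#' @slot mean_log_location,mean_log_scale Log-normal location/scale for
#'   baseline mature-miRNA mean expression.
#' @slot in_region_high Number of deletion-region matures forced to high
#'   expression; the remainder are near silent (see vignette).
#' @slot in_region_high_range Range (min, max) of the uniformly drawn means
#'   for the highly expressed deletion-region matures.
#' @slot in_region_low_mean Mean expression of the remaining deletion-region
#'   matures (kept below the expressed-filter threshold).
#' @slot dispersion Either a single NB dispersion alpha (variance =
#'   mu + alpha mu^2) or a length-2 vector `c(a0, a1)` describing the
#'   hyperbolic mean-dispersion trend alpha(mu) = a1/mu + a0.
#' @slot libsize_sigma Log-normal sigma of per-library size factors.
#' @slot isomir_offset_probs Named numeric vector over offsets "-3".."3";
#'   sampled independently for the 5' and 3' read ends.
#' @slot error_rate Per-base substitution probability.
#' @slot background_fraction Fraction of reads drawn from non-miRNA features.
#' @slot adapter 3' adapter sequence ligated to every insert.
#' @slot adapterless_fraction Fraction of reads synthesized without adapter.
#' @slot read_length Raw read length (single-end).
#' @slot seed Integer seed; every generator stage derives its stream from it.
#' @seealso [simulationConfig()] for the user-facing constructor.
#' @export
setClass("SimulationConfig", representation(
  n_control = "integer",
  n_case = "integer",
  n_mirnas = "integer",
  deletion_interval = "GRanges",
  deletion_effect = "numeric",
  extra_de = "numeric",
  mean_log_location = "numeric",
  mean_log_scale = "numeric",
  in_region_high = "integer",
  in_region_high_range = "numeric",
  in_region_low_mean = "numeric",
  dispersion = "numeric",
  libsize_sigma = "numeric",
  isomir_offset_probs = "numeric",
  error_rate = "numeric",
  background_fraction = "numeric",
  adapter = "character",
  adapterless_fraction = "numeric",
  read_length = "integer",
  seed = "integer"
))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@n_control < 2L || object@n_case < 2L)
    msg <- c(msg, "n_control and n_case must both be >= 2")
  if (object@n_mirnas < 1L)
    msg <- c(msg, "n_mirnas must be >= 1")
  if (object@deletion_effect <= 0)
    msg <- c(msg, "deletion_effect must be > 0")
  probs <- c(object@error_rate, object@background_fraction,
             object@adapterless_fraction, object@isomir_offset_probs)
  if (any(probs < 0 | probs > 1))
    msg <- c(msg, "all probabilities must lie in [0, 1]")
  if (abs(sum(object@isomir_offset_probs) - 1) > 1e-9)
    msg <- c(msg, "isomir_offset_probs must sum to 1")
  if (!identical(names(object@isomir_offset_probs), as.character(-3:3)))
    msg <- c(msg, "isomir_offset_probs must be named '-3'..'3'")
  if (!length(object@dispersion) %in% 1:2 || any(object@dispersion < 0))
    msg <- c(msg, "dispersion must be a nonnegative scalar alpha or c(a0, a1)")
  if (length(object@deletion_interval) != 1L)
    msg <- c(msg, "deletion_interval must be a single interval")
  if (!grepl("^[ACGT]+$", object@adapter))
    msg <- c(msg, "adapter must be a DNA string over {A,C,G,T}")
  if (object@read_length < 15L)
    msg <- c(msg, "read_length must be >= 15")
  if (length(msg)) msg else TRUE
})

#' Toy small-RNA reference (genome, hairpins, annotation)
#'
#' Stand-in for a miRBase-style hairpin reference plus a GENCODE-style gene
#' annotation, generated by [buildToyReference()]. All coordinates are
#' 1-based inclusive; the DNA alphabet is {A,C,G,T}.
#'
#' @slot genome `DNAStringSet` of toy contigs.
#' @slot hairpins `DNAStringSet` of pre-miRNA (hairpin) sequences.
#' @slot matures `GRanges` on hairpin coordinates (seqnames are hairpin ids)
#'   with an `mature_id` metadata column; mature intervals lie within their
#'   hairpin and are 18-25 nt long.
#' @slot loci Genomic `GRanges` of hairpin loci with a `hairpin_id` column;
#'   the genome sequence at each locus equals the hairpin sequence (reverse
#'   complement on the minus strand).
#' @slot gene_features Genomic `GRanges` of non-miRNA gene features with a
#'   `category` column in {protein_coding, lincRNA, snoRNA, tRNA, rRNA,
#'   intergenic}.
#' @export
setClass("ToyReference", representation(
  genome = "DNAStringSet",
  hairpins = "DNAStringSet",
  matures = "GRanges",
  loci = "GRanges",
  gene_features = "GRanges"
))

setValidity("ToyReference", function(object) {
  msg <- character()
  hp_len <- setNames(width(object@hairpins), names(object@hairpins))
  m <- object@matures
  if (length(m)) {
    hp <- as.character(seqnames(m))
    if (!all(hp %in% names(hp_len)))
      msg <- c(msg, "mature intervals reference unknown hairpins")
    else {
      if (any(start(m) < 1L) || any(end(m) > hp_len[hp]))
        msg <- c(msg, "mature intervals must lie within their hairpin")
      if (any(width(m) < 18L | width(m) > 25L))
        msg <- c(msg, "mature lengths must lie in [18, 25]")
    }
    if (anyDuplicated(mcols(m)$mature_id))
      msg <- c(msg, "mature ids must be unique genome-wide")
  }
  gl <- setNames(width(object@genome), names(object@genome))
  loc <- object@loci
  if (length(loc)) {
    ct <- as.character(seqnames(loc))
    if (!all(ct %in% names(gl)))
      msg <- c(msg, "hairpin loci reference unknown contigs")
    else if (any(start(loc) < 1L) || any(end(loc) > gl[ct]))
      msg <- c(msg, "hairpin loci must lie within their contig")
  }
  if (length(object@gene_features) &&
      !all(mcols(object@gene_features)$category %in%
           c("protein_coding", "lincRNA", "snoRNA", "tRNA", "rRNA",
             "intergenic")))
    msg <- c(msg, "unknown gene feature category")
  if (length(msg)) msg else TRUE
})

#' Ground truth of a simulated study
#'
#' Holds the latent quantities behind a simulated dataset: the true
#' mature-by-sample count matrix, the per-mature fold effects applied to the
#' case group, the set of truly differential matures, the baseline means and
#' the per-library size factors. Per-read provenance is produced later, by
#' [synthesizeReads()], because reads only exist at synthesis time.
#'
#' @slot counts Integer matrix, matures x samples.
#' @slot fold Named numeric vector of case-group fold multipliers per mature.
#' @slot true_de Character vector of mature ids with fold != 1.
#' @slot means Named numeric baseline mean expression per mature.
#' @slot size_factors Named numeric per-library scale factors.
#' @slot groups Character vector, "control"/"case" per library.
#' @export
setClass("SmallRnaTruth", representation(
  counts = "matrix",
  fold = "numeric",
  true_de = "character",
  means = "numeric",
  size_factors = "numeric",
  groups = "character"
))

setValidity("SmallRnaTruth", function(object) {
  msg <- character()
  if (any(object@counts < 0) || any(object@counts != round(object@counts)))
    msg <- c(msg, "true counts must be nonnegative integers")
  if (ncol(object@counts) != length(object@groups))
    msg <- c(msg, "one group label per sample is required")
  if (!all(object@true_de %in% rownames(object@counts)))
    msg <- c(msg, "true_de must name rows of the count matrix")
  if (length(msg)) msg else TRUE
})

#' Mature-miRNA counts with read-fate accounting
#'
#' A `SummarizedExperiment` holding the mature-miRNA x sample count matrix
#' produced by [quantifyReads()] (assay `"counts"`), with per-sample
#' assigned-read totals in `colData()$assigned_total` and the per-sample
#' read-fate report (adapterless, length-filtered, miRNA, per-category
#' non-miRNA, ambiguous, unmapped) in `metadata()$read_fates`. The fate
#' tallies partition every input read exactly once.
#'
#' @seealso [readFates()], [assignedTotals()]
#' @export
#' @import SummarizedExperiment
setClass("MirnaCountsExperiment", contains = "SummarizedExperiment")

setValidity("MirnaCountsExperiment", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    cts <- SummarizedExperiment::assay(object, "counts")
    if (any(cts < 0)) msg <- c(msg, "counts must be nonnegative")
    if (!is.null(object$assigned_total) &&
        !isTRUE(all.equal(unname(colSums(cts)),
                          unname(as.numeric(object$assigned_total)))))
      msg <- c(msg, "column sums must equal per-sample assigned totals")
  }
  if (is.null(object$assigned_total))
    msg <- c(msg, "colData must contain 'assigned_total'")
  if (length(msg)) msg else TRUE
})
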