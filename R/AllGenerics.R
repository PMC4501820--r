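#' Per-sample read-fate report
#'
#' @param x A [MirnaCountsExperiment-class].
#' @return A data.frame with one row per (sample, fate) tally; the fates
#'   partition every input read of the sample.
#' @export
setGeneric("readFates", function(x) standardGeneric("readFates"))

#' Per-sample totals of reads finally assigned to mature miRNAs
#'
#' @param x A [MirnaCountsExperiment-class].
#' @return Named numeric vector of assigned-read totals (the RPM
#'   denominator used by [expressedMirnas()]).
#' @export
setGeneric("assignedTotals", function(x) standardGeneric("assignedTotals"))

#' @rdname readFates
setMethod("readFates", "MirnaCountsExperiment", function(x)
  S4Vectors::metadata(x)$read_fates)

#' @rdname assignedTotals
setMethod("assignedTotals", "MirnaCountsExperiment", function(x)
  setNames(as.numeric(x$assigned_total), colnames(x)))

#' Accessors for simulation ground truth
#'
#' @param x A [SmallRnaTruth-class].
#' @return `trueCounts()`: the mature x sample integer count matrix;
#'   `trueDe()`: ids of truly differential matures; `sampleGroups()`: the
#'   "control"/"case" label per library.
#' @export
setGeneric("trueCounts", function(x) standardGeneric("trueCounts"))

#' @rdname trueCounts
#' @export
setGeneric("trueDe", function(x) standardGeneric("trueDe"))

#' @rdname trueCounts
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' @rdname trueCounts
setMethod("trueCounts", "SmallRnaTruth", function(x) x@counts)

#' @rdname trueCounts
setMethod("trueDe", "SmallRnaTruth", function(x) x@true_de)

#' @rdname trueCounts
setMethod("sampleGroups", "SmallRnaTruth", function(x) x@groups)

setMethod("show", "SimulationConfig", function(object) {
  di <- object@deletion_interval
  cat("SimulationConfig:",
      sprintf("%d control vs %d case libraries, %d hairpin genes",
              object@n_control, object@n_case, object@n_mirnas), "\n")
  cat(sprintf("  deletion %s:%d-%d, effect %.2g; adapter %s; seed %d\n",
              as.character(GenomicRanges::seqnames(di)),
              GenomicRanges::start(di), GenomicRanges::end(di),
              object@deletion_effect, object@adapter, object@seed))
  disp <- object@dispersion
  if (length(disp) == 2L)
    cat(sprintf("  dispersion trend alpha(mu) = %.3g/mu + %.3g\n",
                disp[2L], disp[1L]))
  else cat(sprintf("  dispersion alpha = %.3g\n", disp))
})

setMethod("show", "ToyReference", function(object) {
  cat("ToyReference:", length(object@genome), "contigs (",
      sum(width(object@genome)), "bp ),",
      length(object@hairpins), "hairpins,",
      length(object@matures), "matures,",
      length(object@gene_features), "gene features\n")
})

setMethod("show", "SmallRnaTruth", function(object) {
  cat("SmallRnaTruth:", nrow(object@counts), "matures x",
      ncol(object@counts), "samples;",
      length(object@true_de), "truly differential\n")
})
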