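#' Expressed-miRNA filter in reads-per-million
#'
#' A miRNA is expressed when its mean RPM across samples reaches
#' `rpm_threshold` (closed boundary: RPM exactly at the threshold is
#' included). `RPM_ij = count_ij * 1e6 / assigned_total_j`.
#'
#' @param counts Raw count matrix, miRNAs x samples.
#' @param assigned_totals Per-sample totals of assigned reads (the RPM
#'   denominator); must be positive.
#' @param rpm_threshold Expression threshold in RPM (default 1).
#' @return Named logical vector (`TRUE` = expressed); the mean RPM values
#'   are attached as attribute `rpm`.
#' @export
expressedMirnas <- function(counts, assigned_totals, rpm_threshold = 1) {
  if (any(assigned_totals <= 0))
    stop("zero library total; RPM undefined")
  rpm <- rowMeans(sweep(counts, 2L, assigned_totals / 1e6, "/"))
  out <- rpm >= rpm_threshold
  attr(out, "rpm") <- rpm
  out
}

#' Build the deletion-region 2x2 contingency table
#'
#' Restricted to expressed miRNAs on the deletion's contig; a miRNA is
#' in-region iff its mature-locus midpoint lies within the interval
#' (1-based inclusive). Cells: a = in-region DE, b = in-region not-DE,
#' c = out-region DE, d = out-region not-DE.
#'
#' @param expressed Character vector of expressed mature ids.
#' @param de Character vector of (nominally) DE mature ids.
#' @param loci Genomic `GRanges` of mature loci with a `mature_id` column
#'   (see [matureLoci()]), or a data.frame with columns `mature_id`,
#'   `contig`, `start`, `end`.
#' @param interval Deletion interval (`GRanges` or "contig:start-end").
#' @return 2x2 integer matrix with dimnames region x DE status.
#' @export
buildRegionContingency <- function(expressed, de, loci, interval) {
  if (is.character(interval)) interval <- parseInterval(interval)
  if (is(loci, "GRanges"))
    loci <- data.frame(mature_id = mcols(loci)$mature_id,
                       contig = as.character(seqnames(loci)),
                       start = start(loci), end = end(loci))
  loci <- loci[match(expressed, loci$mature_id), , drop = FALSE]
  if (anyNA(loci$mature_id))
    stop("missing locus for expressed miRNA(s): ",
         paste(setdiff(expressed, loci$mature_id), collapse = ", "))
  on_contig <- loci$contig == as.character(seqnames(interval))
  mid <- (loci$start + loci$end) / 2
  inreg <- on_contig & mid >= start(interval) & mid <= end(interval)
  outreg <- on_contig & !inreg
  isde <- loci$mature_id %in% de
  matrix(c(sum(inreg & isde), sum(inreg & !isde),
           sum(outreg & isde), sum(outreg & !isde)),
         nrow = 2L, byrow = TRUE,
         dimnames = list(region = c("in", "out"), DE = c("de", "not_de")))
}

#' Fisher's exact test on a 2x2 table
#'
#' Exact hypergeometric computation with fixed margins: the one-sided
#' p-value is `P(X >= a)` (enrichment of the top-left cell), the two-sided
#' p-value sums the probabilities of all outcomes no more likely than the
#' observed one. Probabilities come from the log-scale hypergeometric pmf,
#' so large margins do not overflow.
#'
#' @param table 2x2 matrix of nonnegative integer counts (or the four cells
#'   `a, b, c, d` row-wise).
#' @return list with `p_one_sided`, `p_two_sided` and the observed table.
#' @examples
#' fisherExactTest(matrix(c(5, 0, 1, 40), 2, byrow = TRUE))
#' @export
fisherExactTest <- function(table) {
  x <- as.integer(table)
  if (length(x) != 4L || any(x < 0))
    stop("need a 2x2 table of nonnegative integer counts")
  a <- x[1L]
  if (is.matrix(table)) {
    b <- table[1L, 2L]; cc <- table[2L, 1L]; d <- table[2L, 2L]
  } else { b <- x[2L]; cc <- x[3L]; d <- x[4L] }
  K <- a + cc           # column-1 margin (successes in the urn)
  n <- a + b            # row-1 margin (draws)
  N <- a + b + cc + d
  lo <- max(0L, n - (N - K)); hi <- min(n, K)
  support <- lo:hi
  logp <- dhyper(support, K, N - K, n, log = TRUE)
  p_one <- sum(exp(logp[support >= a]))
  p_obs <- logp[match(a, support)]
  p_two <- sum(exp(logp[logp <= p_obs + 1e-7]))
  list(p_one_sided = min(p_one, 1), p_two_sided = min(p_two, 1),
       table = if (is.matrix(table)) table
               else matrix(c(a, b, cc, d), 2L, byrow = TRUE))
}

#' Test enrichment of DE miRNAs inside the deletion region
#'
#' Convenience wrapper: filters to expressed miRNAs, builds the
#' deletion-contig contingency table and runs the exact test.
#'
#' @param de_table DE result from [runDifferentialExpression()] (rownames
#'   are mature ids) or a character vector of DE mature ids.
#' @param loci Mature loci (see [buildRegionContingency()]).
#' @param interval Deletion interval.
#' @param counts,assigned_totals Passed to [expressedMirnas()]; when
#'   omitted, every miRNA in `loci` counts as expressed.
#' @param rpm_threshold Expression threshold in RPM.
#' @return list with the contingency `table`, `p_one_sided`,
#'   `p_two_sided` and the expressed set used.
#' @export
testRegionEnrichment <- function(de_table, loci, interval, counts = NULL,
                                 assigned_totals = NULL,
                                 rpm_threshold = 1) {
  de <- if (is.character(de_table)) de_table
        else rownames(de_table)[de_table$nominal]
  if (!is.null(counts)) {
    ex <- expressedMirnas(counts, assigned_totals, rpm_threshold)
    expressed <- rownames(counts)[ex]
  } else {
    expressed <- if (is(loci, "GRanges")) mcols(loci)$mature_id
                 else loci$mature_id
  }
  tab <- buildRegionContingency(expressed, de, loci, interval)
  c(fisherExactTest(tab), list(expressed = expressed))
}
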