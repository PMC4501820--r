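#' Median-of-ratios size factors
#'
#' For each miRNA with no zero count, the geometric mean across samples is
#' the reference; a sample's size factor is the median over those miRNAs of
#' the ratio of its observed count to the reference. Scaling one sample's
#' counts by `c` scales its size factor by `c`.
#'
#' @param counts Numeric matrix, miRNAs x samples (>= 2 samples).
#' @return Named numeric vector of positive per-sample size factors.
#' @examples
#' m <- rbind(a = c(10, 20), b = c(30, 60))
#' sizeFactorsMedianOfRatios(m)  # c(1, 2)/sqrt(2)
#' @export
sizeFactorsMedianOfRatios <- function(counts) {
  stopifnot(ncol(counts) >= 2L)
  pos <- rowSums(counts == 0) == 0L
  if (!any(pos))
    stop("no miRNA with all-positive counts; cannot form the geometric-",
         "mean reference (pseudo-reference fallback is not provided)")
  lg <- rowMeans(log(counts[pos, , drop = FALSE]))
  sf <- apply(counts[pos, , drop = FALSE], 2L,
              function(x) median(exp(log(x) - lg)))
  setNames(sf, colnames(counts))
}

#' Moderated method-of-moments NB dispersion
#'
#' Per-miRNA dispersion is estimated from normalized counts as
#' `alpha_hat = max(0, (s2 - mu) / mu^2)` with `s2` the pooled within-group
#' variance and `mu` the overall mean. A hyperbolic trend
#' `alpha(mu) = a1/mu + a0` is then fitted by least squares on the positive
#' `alpha_hat` of miRNAs with `mu > 1`, with iterative 3-MAD residual
#' trimming (method-of-moments estimates at low means are wildly
#' heavy-tailed and would otherwise dominate the fit). The final dispersion
#' is the average of the per-miRNA estimate and the trend value; zero-mean
#' miRNAs take the trend floor `a0`.
#'
#' @param norm_counts Normalized count matrix, miRNAs x samples.
#' @param groups Character/factor of group labels (each group >= 2).
#' @return list with `alpha` (final per-miRNA dispersions), `alpha_mom`
#'   (raw method-of-moments estimates) and `trend` (`c(a0, a1)`).
#' @export
estimateDispersion <- function(norm_counts, groups) {
  groups <- as.character(groups)
  stopifnot(all(table(groups) >= 2L), length(unique(groups)) == 2L)
  gs <- unique(groups)
  mu <- rowMeans(norm_counts)
  ssq <- 0; dfree <- 0
  for (g in gs) {
    sub <- norm_counts[, groups == g, drop = FALSE]
    ssq <- ssq + rowSums((sub - rowMeans(sub))^2)
    dfree <- dfree + ncol(sub) - 1L
  }
  s2 <- ssq / dfree
  amom <- ifelse(mu > 0, pmax(0, (s2 - mu) / mu^2), NA_real_)
  trend <- fitDispersionTrend(amom, mu)
  atrend <- trend["a1"] / pmax(mu, 1e-8) + trend["a0"]
  alpha <- ifelse(mu > 0, (ifelse(is.na(amom), atrend, amom) + atrend) / 2,
                  trend["a0"])
  list(alpha = unname(alpha), alpha_mom = unname(amom),
       trend = trend)
}

fitDispersionTrend <- function(amom, mu) {
  keep <- is.finite(amom) & amom > 0 & mu > 1
  if (sum(keep) < 3L)
    return(c(a0 = max(mean(amom[is.finite(amom)], na.rm = TRUE), 1e-4,
                      na.rm = TRUE), a1 = 0))
  x <- 1 / mu[keep]; y <- amom[keep]
  fit <- NULL
  for (it in 1:3) {
    fit <- lm(y ~ x)
    r <- resid(fit)
    s <- mad(r)
    ok <- abs(r) <= 3 * max(s, 1e-8)
    if (all(ok)) break
    x <- x[ok]; y <- y[ok]
  }
  c(a0 = max(unname(coef(fit)[1L]), 1e-4),
    a1 = max(unname(coef(fit)[2L]), 0))
}

#' Per-miRNA negative-binomial Wald test
#'
#' Group means of normalized counts are compared on the log2 scale;
#' `log2FC = log2(m_control / m_case)`, so a positive value means lower
#' expression in the case group. The standard error comes from the delta
#' method under NB(mean, alpha) with each group's sample size:
#' `SE^2 = [(1/m_ctrl + alpha)/n_ctrl + (1/m_case + alpha)/n_case] / ln(2)^2`.
#' A pseudo-mean of 0.5 is added to both groups only when either group
#' mean is exactly zero; if both are zero the miRNA gets `log2FC = 0`,
#' `p = 1`. p-values are two-sided tails of `z = log2FC / SE` under a t
#' reference with `2 * (n_ctrl + n_case - 2)` degrees of freedom: the
#' moderated dispersion is half per-miRNA estimate (which carries the
#' residual degrees of freedom) and half fitted trend, so the effective
#' degrees of freedom are about twice the residual ones. A plain normal
#' tail ignores the dispersion-estimation noise and is measurably
#' anticonservative at these sample sizes (see the methods vignette).
#'
#' @param counts Raw count matrix, miRNAs x samples.
#' @param size_factors Per-sample size factors.
#' @param dispersion Per-miRNA dispersion vector (see
#'   [estimateDispersion()]).
#' @param groups Group labels; `reference` names the control level.
#' @param reference Reference (control) group label.
#' @return data.frame with `mean_control`, `mean_case`, `log2FC`, `stat`,
#'   `pvalue` per miRNA.
#' @export
nbWaldTest <- function(counts, size_factors, dispersion, groups,
                       reference = "control") {
  groups <- as.character(groups)
  nc <- sweep(counts, 2L, size_factors, "/")
  g1 <- groups == reference
  n1 <- sum(g1); n2 <- sum(!g1)
  m1 <- rowMeans(nc[, g1, drop = FALSE])
  m2 <- rowMeans(nc[, !g1, drop = FALSE])
  zero <- m1 == 0 | m2 == 0
  lfc <- ifelse(zero, log2((m1 + 0.5) / (m2 + 0.5)), log2(m1 / m2))
  se <- sqrt((1 / pmax(m1, 0.5) + dispersion) / n1 +
             (1 / pmax(m2, 0.5) + dispersion) / n2) / log(2)
  z <- lfc / se
  dfree <- 2L * (n1 + n2 - 2L)
  p <- 2 * pt(-abs(z), dfree)
  both0 <- m1 == 0 & m2 == 0
  lfc[both0] <- 0; z[both0] <- 0; p[both0] <- 1
  data.frame(mean_control = m1, mean_case = m2, log2FC = lfc, stat = z,
             pvalue = p, row.names = rownames(counts))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment with cumulative-minimum
#' enforcement; `m` defaults to the number of p-values but may be larger
#' when the list is a filtered subset of the tests actually performed.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param m Number of tests.
#' @return Adjusted p-values in the input order.
#' @examples
#' bhAdjust(c(0.001, 0.01, 0.03, 0.04))  # 0.004 0.020 0.040 0.040
#' @export
bhAdjust <- function(p, m = length(p)) {
  if (!length(p)) return(numeric(0))
  stopifnot(all(p >= 0 & p <= 1), m >= length(p))
  p.adjust(p, method = "BH", n = m)
}

#' Flag differentially expressed miRNAs
#'
#' Applies the calling thresholds: nominal significance at `p < p_cut`
#' with fold change `2^|log2FC| > fold_cut`, and genome-wide significance
#' at `p_adj < fdr_cut`.
#'
#' @param table data.frame with columns `log2FC`, `pvalue` and `padj`.
#' @param p_cut Nominal p-value cutoff (default 0.01).
#' @param fold_cut Fold-change cutoff (default 1.5).
#' @param fdr_cut FDR cutoff for genome-wide significance (default 0.05).
#' @return The table with logical `nominal` and `genomewide` columns,
#'   plus a `summary` attribute: total/down/up nominal counts (down means
#'   positive `log2FC`, i.e. lower in the case group) and genome-wide
#'   count.
#' @export
callDE <- function(table, p_cut = 0.01, fold_cut = 1.5, fdr_cut = 0.05) {
  if (!nrow(table)) {
    attr(table, "summary") <- c(total = 0L, down = 0L, up = 0L,
                                genomewide = 0L)
    return(table)
  }
  table$nominal <- table$pvalue < p_cut & 2^abs(table$log2FC) > fold_cut
  table$genomewide <- table$padj < fdr_cut
  attr(table, "summary") <- c(
    total = sum(table$nominal),
    down = sum(table$nominal & table$log2FC > 0),
    up = sum(table$nominal & table$log2FC < 0),
    genomewide = sum(table$genomewide))
  table
}

#' Spearman sample-correlation QC
#'
#' Rank-based correlation (average ranks on ties) between every pair of
#' samples of a normalized count matrix; constant samples yield `NA`
#' against all others.
#'
#' @param norm_counts Normalized count matrix, miRNAs x samples (>= 2).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
qcSpearman <- function(norm_counts) {
  stopifnot(ncol(norm_counts) >= 2L)
  rho <- suppressWarnings(cor(norm_counts, method = "spearman"))
  diag(rho) <- 1
  rho
}

#' Run the negative-binomial differential-expression analysis
#'
#' Drops miRNAs with zero counts in every sample, normalizes by
#' median-of-ratios size factors, estimates moderated dispersions, applies
#' the per-miRNA Wald test, adjusts p-values by Benjamini-Hochberg over the
#' number tested, and flags DE calls.
#'
#' @param x A [MirnaCountsExperiment-class] or raw count matrix.
#' @param groups Group labels per sample ("control"/"case"); taken from
#'   `colData()$group` when `x` is an experiment and `groups` is NULL.
#' @param exclude_samples Optional sample ids to drop before testing
#'   (subset re-analysis).
#' @param p_cut,fold_cut,fdr_cut Calling thresholds, see [callDE()].
#' @param reference Control group label.
#' @return data.frame (one row per tested miRNA, ordered by p-value) with
#'   normalized group means, `log2FC` (positive = lower in case), `stat`,
#'   `pvalue`, `padj`, `nominal`, `genomewide`; attributes `summary`,
#'   `size_factors`, `dispersion_trend` and `m_tested`.
#' @export
runDifferentialExpression <- function(x, groups = NULL,
                                      exclude_samples = NULL,
                                      p_cut = 0.01, fold_cut = 1.5,
                                      fdr_cut = 0.05,
                                      reference = "control") {
  if (is(x, "MirnaCountsExperiment")) {
    counts <- SummarizedExperiment::assay(x, "counts")
    if (is.null(groups)) groups <- x$group
  } else counts <- as.matrix(x)
  if (is.null(groups)) stop("group labels are required")
  if (p_cut <= 0 || p_cut > 1 || fdr_cut <= 0 || fdr_cut > 1 ||
      fold_cut < 1)
    stop("invalid thresholds: need 0 < p_cut, fdr_cut <= 1 and fold_cut >= 1")
  groups <- setNames(as.character(groups), colnames(counts))
  if (!is.null(exclude_samples)) {
    keep <- !colnames(counts) %in% exclude_samples
    counts <- counts[, keep, drop = FALSE]
    groups <- groups[keep]
  }
  expressed <- rowSums(counts) > 0
  counts <- counts[expressed, , drop = FALSE]

  sf <- sizeFactorsMedianOfRatios(counts)
  nc <- sweep(counts, 2L, sf, "/")
  disp <- estimateDispersion(nc, groups)
  res <- nbWaldTest(counts, sf, disp$alpha, groups, reference)
  res$padj <- bhAdjust(res$pvalue)
  res <- callDE(res, p_cut, fold_cut, fdr_cut)
  summ <- attr(res, "summary")
  res <- res[order(res$pvalue), ]
  attr(res, "summary") <- summ
  attr(res, "size_factors") <- sf
  attr(res, "dispersion_trend") <- disp$trend
  attr(res, "m_tested") <- nrow(res)
  res
}
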