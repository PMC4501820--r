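#' Relative expression by the 2^-ddCt method with two normalizers
#'
#' Per sample, the Ct of each assay is the mean of its replicate wells;
#' `dCt = Ct_target - mean(Ct_normalizers)` (the two normalizer Cts are
#' combined by arithmetic mean, equivalent to a geometric mean of
#' abundances at amplification efficiency 2). `ddCt` is the difference of
#' group-mean dCt (case minus reference), and the group fold change is
#' `2^-ddCt`. Per-sample folds, each normalized to the reference-group
#' mean dCt, feed a pooled two-sample t-test; group dispersion is reported
#' both as the SD of per-sample folds and as the SD of per-sample dCt.
#'
#' @param measurements Long-format data.frame with columns `sample`,
#'   `group`, `assay`, `ct` (one row per replicate well).
#' @param target Target assay id.
#' @param normalizers Character vector of normalizer assay ids (e.g.
#'   SNORD48 and U6).
#' @param reference_group Reference (control) group label.
#' @return list with `per_sample` (sample, group, per-normalizer dCt,
#'   combined dCt, fold), `ddct`, `fold`, `ttest` (on per-sample folds,
#'   case vs reference) and `group_stats`.
#' @export
deltaDeltaCt <- function(measurements, target, normalizers,
                         reference_group = "control") {
  need <- c(target, normalizers)
  samples <- unique(measurements$sample)
  ct <- aggregate(ct ~ sample + group + assay, measurements, mean)
  for (s in samples) {
    have <- ct$assay[ct$sample == s]
    miss <- setdiff(need, have)
    if (length(miss))
      stop("sample ", s, " is missing assay(s): ",
           paste(miss, collapse = ", "))
  }
  wide <- reshape(ct[ct$assay %in% need, ],
                  idvar = c("sample", "group"), timevar = "assay",
                  direction = "wide")
  names(wide) <- sub("^ct\\.", "", names(wide))
  norm_ct <- rowMeans(wide[, normalizers, drop = FALSE])
  per <- data.frame(sample = wide$sample, group = wide$group,
                    stringsAsFactors = FALSE)
  for (nm in normalizers)
    per[[paste0("dct_", nm)]] <- wide[[target]] - wide[[nm]]
  per$dct <- wide[[target]] - norm_ct

  ref <- per$group == reference_group
  if (!any(ref)) stop("no sample in reference group '", reference_group, "'")
  ref_mean <- mean(per$dct[ref])
  case_mean <- mean(per$dct[!ref])
  ddct <- case_mean - ref_mean
  per$fold <- 2^-(per$dct - ref_mean)

  tt <- twoSampleTTest(per$fold[!ref], per$fold[ref])
  gs <- do.call(rbind, lapply(split(per, per$group), function(d)
    data.frame(group = d$group[1L], n = nrow(d),
               mean_fold = mean(d$fold), sd_fold = sd(d$fold),
               mean_dct = mean(d$dct), sd_dct = sd(d$dct))))
  rownames(gs) <- NULL
  list(per_sample = per, ddct = ddct, fold = 2^-ddct, ttest = tt,
       group_stats = gs)
}

#' Pooled two-sample Student's t-test
#'
#' Equal-variance t statistic with `df = nA + nB - 2`. Both the two-tailed
#' p-value and the one-tailed p-value for the alternative
#' `mean(a) > mean(b)` are returned (the one-tailed value halves the
#' two-tailed p when the observed difference points that way).
#'
#' @param a,b Numeric vectors (each length >= 2).
#' @return list with `statistic`, `df`, `p_two_sided`, `p_one_sided`.
#' @export
twoSampleTTest <- function(a, b) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  if (var(a) == 0 && var(b) == 0) {
    df <- length(a) + length(b) - 2L
    if (mean(a) == mean(b))
      return(list(statistic = 0, df = df, p_two_sided = 1,
                  p_one_sided = 0.5))
    t <- sign(mean(a) - mean(b)) * Inf
    return(list(statistic = t, df = df, p_two_sided = 0,
                p_one_sided = if (t > 0) 0 else 1))
  }
  tt <- t.test(a, b, var.equal = TRUE)
  t <- unname(tt$statistic); df <- unname(tt$parameter)
  p2 <- tt$p.value
  list(statistic = t, df = df, p_two_sided = p2,
       p_one_sided = if (t > 0) p2 / 2 else 1 - p2 / 2)
}

#' Cohort demographic summary
#'
#' Per-group arithmetic mean and sample standard deviation (n - 1
#' denominator) of age, group sizes and sex counts; values are returned at
#' full precision (round only for presentation).
#'
#' @param table data.frame with columns `subject`, `age`, `sex`, `group`.
#' @return data.frame with one row per group: `n`, `mean_age`, `sd_age`
#'   (`NA` for single-subject groups), `n_female`, `n_male`.
#' @export
cohortSummary <- function(table) {
  stopifnot(all(table$age > 0))
  out <- do.call(rbind, lapply(split(table, table$group), function(d)
    data.frame(group = d$group[1L], n = nrow(d), mean_age = mean(d$age),
               sd_age = if (nrow(d) > 1L) sd(d$age) else NA_real_,
               n_female = sum(d$sex == "F"), n_male = sum(d$sex == "M"),
               stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}
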