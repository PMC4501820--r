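simulateNbMatrix <- function(G, n1, n2, alpha, mu = NULL, fold = NULL,
                             libsize_sigma = 0.2, seed = 1,
                             meanlog = log(200), sdlog = 1.2) {
  set.seed(seed)
  if (is.null(mu)) mu <- rlnorm(G, meanlog, sdlog)
  if (is.null(fold)) fold <- rep(1, G)
  sf <- exp(rnorm(n1 + n2, 0, libsize_sigma))
  groups <- rep(c("control", "case"), c(n1, n2))
  counts <- sapply(seq_len(n1 + n2), function(j) {
    f <- if (groups[j] == "case") fold else rep(1, G)
    m <- mu * sf[j] * f
    if (all(alpha == 0)) rpois(G, m) else rnbinom(G, mu = m, size = 1 / alpha)
  })
  rownames(counts) <- sprintf("m%04d", seq_len(G))
  colnames(counts) <- sprintf("s%02d", seq_len(n1 + n2))
  list(counts = counts, groups = groups, mu = mu)
}

test_that("median-of-ratios size factors match hand computations", {
  m <- matrix(c(10, 10, 40, 40, 90, 90), nrow = 3, byrow = TRUE,
              dimnames = list(letters[1:3], c("A", "B")))
  expect_equal(unname(sizeFactorsMedianOfRatios(m)), c(1, 1))

  m2 <- m; m2[, "B"] <- 2 * m2[, "A"]
  expect_equal(unname(sizeFactorsMedianOfRatios(m2)),
               c(1 / sqrt(2), sqrt(2)))

  # a row containing a zero is excluded from the median
  m3 <- rbind(m2, d = c(0, 1000))
  expect_equal(sizeFactorsMedianOfRatios(m3),
               sizeFactorsMedianOfRatios(m2))

  expect_error(sizeFactorsMedianOfRatios(
    matrix(c(0, 5, 3, 0), 2)), "all-positive")

  # invariance: scaling one sample by c scales its factor by c
  sf <- sizeFactorsMedianOfRatios(m2)
  m4 <- m2; m4[, "A"] <- m4[, "A"] * 7
  sf4 <- sizeFactorsMedianOfRatios(m4)
  expect_equal(sf4[["A"]] / sf[["A"]], 7 * sf4[["B"]] / sf[["B"]] / 1,
               tolerance = 1e-12)
})

test_that("size factors agree with the reference implementation", {
  d <- simulateNbMatrix(200, 5, 5, alpha = 0.1, seed = 9)
  ours <- sizeFactorsMedianOfRatios(d$counts)
  ref <- DESeq2::estimateSizeFactorsForMatrix(d$counts)
  # same estimator up to the overall scale convention and the even-count
  # median interpolation (DESeq2 interpolates on the log scale)
  expect_equal(unname(ours / ours[1]), unname(ref / ref[1]),
               tolerance = 1e-3)
})

test_that("dispersion estimation recovers the generative regime", {
  d <- simulateNbMatrix(500, 9, 7, alpha = 0, libsize_sigma = 0, seed = 2)
  est <- estimateDispersion(d$counts, d$groups)
  expect_lt(median(est$alpha_mom, na.rm = TRUE), 0.02)

  d1 <- simulateNbMatrix(500, 9, 7, alpha = 0.1, libsize_sigma = 0,
                         seed = 3)
  est1 <- estimateDispersion(d1$counts, d1$groups)
  expect_gt(median(est1$alpha), 0.05)
  expect_lt(median(est1$alpha), 0.2)

  cst <- matrix(rep(c(5, 9), each = 8), nrow = 2, byrow = TRUE)
  est2 <- estimateDispersion(cst, rep(c("control", "case"), each = 4))
  expect_equal(est2$alpha_mom, c(0, 0))
})

test_that("Wald test is null-centered and detects a two-fold change", {
  counts <- matrix(rep(c(100, 200, 50), 8), nrow = 3,
                   dimnames = list(c("a", "b", "c"), NULL))
  groups <- rep(c("control", "case"), each = 4)
  res <- nbWaldTest(counts, rep(1, 8), rep(0.1, 3), groups)
  expect_equal(res$log2FC, rep(0, 3))
  expect_equal(res$pvalue, rep(1, 3))

  # both groups zero
  z <- nbWaldTest(matrix(0, 1, 8), rep(1, 8), 0.1, groups)
  expect_equal(c(z$log2FC, z$pvalue), c(0, 1))

  # 2-fold decrease in case at mean 500, alpha = 0.05
  G <- 300
  d <- simulateNbMatrix(G, 9, 7, alpha = 0.05, mu = rep(500, G),
                        fold = rep(0.5, G), libsize_sigma = 0, seed = 4)
  est <- nbWaldTest(d$counts, rep(1, 16), rep(0.05, G), d$groups)
  expect_lt(abs(mean(est$log2FC) - 1), 0.2)
  expect_gte(mean(est$pvalue < 0.01), 0.9)
})

test_that("BH adjustment agrees with the brute-force step-up", {
  expect_equal(bhAdjust(c(0.001, 0.01, 0.03, 0.04)),
               c(0.004, 0.02, 0.04, 0.04))
  expect_equal(bhAdjust(0.37), 0.37)
  expect_identical(bhAdjust(numeric(0)), numeric(0))

  set.seed(5)
  for (i in 1:1000) {
    n <- sample(1:40, 1)
    p <- round(runif(n), 3)
    m <- n + sample(0:20, 1)
    got <- bhAdjust(p, m)
    expect_equal(got, bruteForceBH(p, m), tolerance = 1e-12)
    o <- order(p)
    expect_true(all(diff(got[o]) >= -1e-12))  # monotone in rank
  }
})

test_that("DE calling reproduces threshold semantics", {
  tab <- data.frame(log2FC = c(1.2, -0.9, 0.3, 2),
                    pvalue = c(0.001, 0.005, 0.0001, 0.2),
                    padj = c(0.01, 0.2, 0.5, 0.9))
  out <- callDE(tab)
  expect_identical(out$nominal, c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(out$genomewide, c(TRUE, FALSE, FALSE, FALSE))
  s <- attr(out, "summary")
  expect_identical(unname(s), c(2L, 1L, 1L, 1L))

  empty <- callDE(tab[0, ])
  expect_identical(unname(attr(empty, "summary")), rep(0L, 4))
})

test_that("Spearman QC is rank-invariant and near 1 for replicates", {
  m <- cbind(a = c(1, 5, 2, 9, 3), b = c(1, 5, 2, 9, 3))
  expect_equal(qcSpearman(m)["a", "b"], 1)
  m2 <- cbind(a = c(1, 5, 2, 9, 3), b = exp(c(1, 5, 2, 9, 3)))
  expect_equal(qcSpearman(m2)["a", "b"], 1)

  d <- simulateNbMatrix(400, 4, 4, alpha = 0.05, libsize_sigma = 0.1,
                        seed = 6)
  rho <- qcSpearman(sweep(d$counts, 2, sizeFactorsMedianOfRatios(d$counts),
                          "/"))
  expect_gt(min(rho), 0.8)

  cst <- cbind(a = rep(3, 5), b = c(1, 4, 2, 8, 5))
  expect_true(is.na(qcSpearman(cst)["a", "b"]))
})

test_that("scaling one library leaves fold changes and p-values unchanged", {
  d <- simulateNbMatrix(300, 5, 5, alpha = 0.05, seed = 7)
  r1 <- runDifferentialExpression(d$counts, d$groups)
  d2 <- d$counts
  d2[, 3] <- d2[, 3] * 5L
  r2 <- runDifferentialExpression(d2, d$groups)[rownames(r1), ]
  # fold changes are exactly scale-free; p-values only approximately so,
  # because the Poisson component of the NB variance lives on the raw
  # count scale (see the methods vignette)
  expect_equal(r1$log2FC, r2$log2FC, tolerance = 1e-9)
  expect_equal(r1$pvalue, r2$pvalue, tolerance = 0.02)
  sf1 <- attr(r1, "size_factors"); sf2 <- attr(r2, "size_factors")
  expect_equal(unname(sf2[3] / sf1[3] / (sf2[1] / sf1[1])), 5,
               tolerance = 1e-9)
})

test_that("the default deletion simulation recovers the in-region signal", {
  for (s in c(101, 202, 303)) {
    cfg <- simulationConfig(seed = s)
    ref <- buildToyReference(cfg)
    tr <- simulateCounts(ref, cfg)
    hi <- names(tr@fold)[tr@fold == cfg@deletion_effect & tr@means >= 100]
    expect_length(hi, 5L)
    res <- runDifferentialExpression(tr@counts, tr@groups)
    expect_true(all(res[hi, "nominal"]))
    expect_true(all(res[hi, "log2FC"] > 0))
  }
})

test_that("sample exclusion and threshold validation work", {
  d <- simulateNbMatrix(100, 4, 4, alpha = 0.05, seed = 8)
  r <- runDifferentialExpression(d$counts, d$groups,
                                 exclude_samples = c("s01", "s08"))
  expect_identical(length(attr(r, "size_factors")), 6L)
  expect_error(runDifferentialExpression(d$counts, d$groups, p_cut = 2),
               "thresholds")
})
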