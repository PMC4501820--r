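test_that("reference construction is deterministic and places hairpins in the deletion", {
  cfg <- simulationConfig(n_mirnas = 10L, seed = 42L)
  r1 <- buildToyReference(cfg)
  r2 <- buildToyReference(cfg)
  expect_identical(as.character(r1@genome), as.character(r2@genome))
  expect_identical(as.character(r1@hairpins), as.character(r2@hairpins))
  expect_identical(r1@loci, r2@loci)

  di <- cfg@deletion_interval
  loc <- r1@loci
  inside <- as.character(seqnames(loc)) == as.character(seqnames(di)) &
    start(loc) >= start(di) & end(loc) <= end(di)
  expect_gte(sum(inside), 2L)  # >= 20% of 10 hairpins

  # genome carries the hairpin sequence at each locus (RC on minus strand)
  gen <- as.character(r1@genome)
  for (i in seq_along(loc)) {
    sub <- substr(gen[[as.character(seqnames(loc))[i]]], start(loc)[i],
                  end(loc)[i])
    hp <- as.character(r1@hairpins[[mcols(loc)$hairpin_id[i]]])
    if (as.character(strand(loc))[i] == "-")
      hp <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(hp)))
    expect_identical(sub, hp)
  }
})

test_that("mature intervals respect hairpin bounds across many seeds", {
  for (s in seq_len(300)) {
    ref <- buildToyReference(simulationConfig(n_mirnas = 8L, seed = s))
    hp_len <- setNames(width(ref@hairpins), names(ref@hairpins))
    m <- ref@matures
    expect_true(all(start(m) >= 1L))
    expect_true(all(end(m) <= hp_len[as.character(seqnames(m))]))
    expect_true(all(width(m) >= 18L & width(m) <= 25L))
    expect_false(anyDuplicated(mcols(m)$mature_id) > 0)
  }
})

test_that("counts follow the negative binomial model", {
  # alpha = 0 reduces to Poisson: variance tracks the mean
  cfg0 <- simulationConfig(n_mirnas = 250L, n_control = 8L, n_case = 8L,
                           deletion_effect = 1, dispersion = 0,
                           libsize_sigma = 0, in_region_high = 0L,
                           in_region_low_mean = 50, seed = 9L)
  ref <- buildToyReference(cfg0)
  tr0 <- simulateCounts(ref, cfg0)
  mu <- rowMeans(tr0@counts)
  v <- apply(tr0@counts, 1L, var)
  keep <- mu > 5
  expect_gt(sum(keep), 200L)
  ratio <- mean(v[keep] / mu[keep])
  expect_lt(abs(ratio - 1), 0.15)

  # constant alpha: regression slope of (s2 - mu) on mu^2 recovers alpha
  cfg1 <- simulationConfig(n_mirnas = 450L, n_control = 8L, n_case = 8L,
                           deletion_effect = 1, dispersion = 0.1,
                           libsize_sigma = 0, in_region_high = 0L,
                           in_region_low_mean = 50, seed = 10L)
  ref1 <- buildToyReference(cfg1)
  tr1 <- simulateCounts(ref1, cfg1)
  mu <- rowMeans(tr1@counts)
  v <- apply(tr1@counts, 1L, var)
  keep <- mu > 20
  expect_gt(sum(keep), 500L)
  slope <- coef(lm(I(v[keep] - mu[keep]) ~ 0 + I(mu[keep]^2)))[[1]]
  expect_lt(abs(slope - 0.1) / 0.1, 0.2)
})

test_that("the deletion halves case-group means of in-region miRNAs", {
  cfg <- simulationConfig(n_mirnas = 500L, n_control = 8L, n_case = 8L,
                          dispersion = 0.05, libsize_sigma = 0,
                          in_region_high = 100L,
                          in_region_high_range = c(500, 1500), seed = 2L)
  ref <- buildToyReference(cfg)
  tr <- simulateCounts(ref, cfg)
  hi <- tr@fold == 0.5 & tr@means >= 400
  expect_gte(sum(hi), 80L)
  ctrl <- rowMeans(tr@counts[hi, tr@groups == "control"])
  case <- rowMeans(tr@counts[hi, tr@groups == "case"])
  expect_true(mean(case / ctrl) > 0.45 && mean(case / ctrl) < 0.55)

  # no deletion effect and no extra folds: nothing is truly DE
  cfg1 <- simulationConfig(n_mirnas = 30L, deletion_effect = 1, seed = 3L)
  ref1 <- buildToyReference(cfg1)
  tr1 <- simulateCounts(ref1, cfg1)
  expect_length(tr1@true_de, 0L)

  # extra per-mature folds compose with the deletion effect
  some <- mcols(ref1@matures)$mature_id[1:2]
  cfg2 <- simulationConfig(n_mirnas = 30L, deletion_effect = 1, seed = 3L,
                           extra_de = setNames(c(2, 0.25), some))
  tr2 <- simulateCounts(ref1, cfg2)
  expect_setequal(tr2@true_de, some)
  expect_equal(unname(tr2@fold[some]), c(2, 0.25))
})

test_that("read synthesis is deterministic and respects the clean limit", {
  cfg <- cleanConfig(seed = 7L)
  ref <- buildToyReference(cfg)
  tr <- simulateCounts(ref, cfg)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  r1 <- synthesizeReads(tr, ref, cfg, d1)
  r2 <- synthesizeReads(tr, ref, cfg, d2)
  for (s in names(r1$fastq))
    expect_identical(readLines(r1$fastq[[s]]), readLines(r2$fastq[[s]]))

  # with zero offsets/errors, each read starts with its mature sequence
  hp <- as.character(ref@hairpins)
  mat <- ref@matures
  mat_seq <- setNames(substr(hp[as.character(seqnames(mat))], start(mat),
                             end(mat)), mcols(mat)$mature_id)
  fq <- readLines(r1$fastq[[1]])
  reads <- fq[seq(2L, length(fq), by = 4L)]
  ids <- sub("^@", "", fq[seq(1L, length(fq), by = 4L)])
  prov <- r1$provenance[r1$provenance$sample == names(r1$fastq)[1L], ]
  ord <- match(ids, prov$read)
  expect_false(anyNA(ord))
  ms <- mat_seq[prov$origin_id[ord]]
  expect_true(all(substr(reads, 1L, nchar(ms)) == ms))
})

test_that("the adapterless fraction matches its nominal rate", {
  cfg <- simulationConfig(n_mirnas = 40L, n_control = 3L, n_case = 3L,
                          mean_log_location = log(120),
                          background_fraction = 0.1, seed = 13L)
  ref <- buildToyReference(cfg)
  tr <- simulateCounts(ref, cfg)
  d <- withr::local_tempdir()
  rs <- synthesizeReads(tr, ref, cfg, d)
  n <- nrow(rs$provenance)
  expect_gt(n, 5e4)
  frac <- mean(rs$provenance$adapterless)
  expect_lt(abs(frac - 0.07), 0.005)
})

test_that("reference files round-trip through FASTA/GFF3", {
  cfg <- simulationConfig(n_mirnas = 12L, seed = 21L)
  ref <- buildToyReference(cfg)
  d <- withr::local_tempdir()
  writeToyReference(ref, d)
  ref2 <- readToyReference(d)
  expect_identical(as.character(ref@genome), as.character(ref2@genome))
  expect_identical(as.character(ref@hairpins), as.character(ref2@hairpins))
  expect_identical(mcols(ref@matures)$mature_id,
                   mcols(ref2@matures)$mature_id)
  expect_equal(start(ref@matures), start(ref2@matures))
  expect_equal(start(ref@loci), start(ref2@loci))
  expect_identical(as.character(strand(ref@loci)),
                   as.character(strand(ref2@loci)))
  expect_identical(mcols(ref@gene_features)$category,
                   mcols(ref2@gene_features)$category)
})

test_that("invalid configurations are rejected", {
  expect_error(simulationConfig(n_control = 1L), "n_control")
  expect_error(simulationConfig(deletion_effect = 0), "deletion_effect")
  expect_error(simulationConfig(error_rate = 1.5), "probabilities")
  expect_error(simulationConfig(dispersion = -0.1), "dispersion")
  cfg <- simulationConfig(
    n_mirnas = 5L,
    deletion_interval = GenomicRanges::GRanges(
      "chr22", IRanges::IRanges(-5, 1000)))
  expect_error(buildToyReference(cfg), "configuration error")
})
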