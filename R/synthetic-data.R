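#' Construct a simulation configuration
#'
#' Defaults emulate the study design being modeled: 9 control vs 7 patient
#' libraries, a hemizygous deletion halving the expression of
#' deletion-region miRNAs, a handful of highly expressed deletion-region
#' matures with the remainder near silence, isomiR 5'/3' end offsets, the
#' NEBNext 3' adapter `TGGAATTCTCGGGTGCCAAGG`, ~7% adapterless reads and
#' 50 bp single-end reads. See the methods vignette for the rationale
#' behind each default.
#'
#' @param n_control,n_case Libraries per group.
#' @param n_mirnas Number of hairpin genes in the toy reference.
#' @param deletion_interval Deletion as `"contig:start-end"` string or a
#'   `GRanges` of length 1.
#' @param deletion_effect Fold multiplier on deletion-region miRNA means in
#'   case samples.
#' @param extra_de Named numeric vector of additional fold effects keyed by
#'   mature id (multiplicative with any deletion effect).
#' @param mean_log_location,mean_log_scale Log-normal parameters of baseline
#'   mean expression.
#' @param in_region_high Number of deletion-region matures forced to high
#'   expression.
#' @param in_region_high_range Uniform range for those high means.
#' @param in_region_low_mean Mean for the remaining deletion-region matures.
#' @param dispersion Scalar NB dispersion alpha, or `c(a0, a1)` for the
#'   trend alpha(mu) = a1/mu + a0.
#' @param libsize_sigma Log-normal sigma of library size factors.
#' @param isomir_offset_probs Named probabilities over offsets `-3..3`.
#' @param error_rate Per-base substitution probability.
#' @param background_fraction Fraction of reads from non-miRNA features.
#' @param adapter 3' adapter DNA string.
#' @param adapterless_fraction Fraction of reads without adapter.
#' @param read_length Raw read length.
#' @param seed Integer RNG seed.
#' @return A [SimulationConfig-class] object.
#' @examples
#' cfg <- simulationConfig(n_mirnas = 20, seed = 7)
#' cfg
#' @export
simulationConfig <- function(n_control = 9L,
                             n_case = 7L,
                             n_mirnas = 300L,
                             deletion_interval = "chr22:10001-40000",
                             deletion_effect = 0.5,
                             extra_de = numeric(),
                             mean_log_location = log(200),
                             mean_log_scale = 1.2,
                             in_region_high = 5L,
                             in_region_high_range = c(200, 1000),
                             in_region_low_mean = 0.2,
                             dispersion = c(0.02, 2),
                             libsize_sigma = 0.2,
                             isomir_offset_probs = c(
                               "-3" = 0.015, "-2" = 0.035, "-1" = 0.1,
                               "0" = 0.7,
                               "1" = 0.1, "2" = 0.035, "3" = 0.015),
                             error_rate = 0.005,
                             background_fraction = 0.15,
                             adapter = "TGGAATTCTCGGGTGCCAAGG",
                             adapterless_fraction = 0.07,
                             read_length = 50L,
                             seed = 1L) {
  if (is.character(deletion_interval))
    deletion_interval <- parseInterval(deletion_interval)
  new("SimulationConfig",
      n_control = as.integer(n_control), n_case = as.integer(n_case),
      n_mirnas = as.integer(n_mirnas),
      deletion_interval = deletion_interval,
      deletion_effect = deletion_effect, extra_de = extra_de,
      mean_log_location = mean_log_location,
      mean_log_scale = mean_log_scale,
      in_region_high = as.integer(in_region_high),
      in_region_high_range = in_region_high_range,
      in_region_low_mean = in_region_low_mean,
      dispersion = dispersion, libsize_sigma = libsize_sigma,
      isomir_offset_probs = isomir_offset_probs,
      error_rate = error_rate, background_fraction = background_fraction,
      adapter = adapter, adapterless_fraction = adapterless_fraction,
      read_length = as.integer(read_length), seed = as.integer(seed))
}

#' Parse a "contig:start-end" interval string
#'
#' @param x Interval string, e.g. `"chr22:18500000-21900000"`. Commas in the
#'   coordinates are allowed.
#' @return A `GRanges` of length 1 (1-based inclusive).
#' @export
parseInterval <- function(x) {
  m <- regmatches(x, regexec("^([^:]+):([0-9,]+)-([0-9,]+)$", x))[[1L]]
  if (length(m) != 4L)
    stop("cannot parse interval '", x, "'; expected contig:start-end")
  GRanges(m[2L], IRanges(as.numeric(gsub(",", "", m[3L])),
                         as.numeric(gsub(",", "", m[4L]))))
}

randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Place k hairpins without overlap inside [a, b] using jittered even slots.
placeHairpins <- function(a, b, lens) {
  k <- length(lens)
  if (k == 0L) return(integer())
  w <- (b - a + 1L) %/% k
  if (w < max(lens) + 2L)
    stop("configuration error: interval ", a, "-", b,
         " cannot fit ", k, " hairpins")
  vapply(seq_len(k), function(i)
    a + (i - 1L) * w + sample.int(w - lens[i] - 1L, 1L), numeric(1))
}

#' Build a toy small-RNA reference around a deletion interval
#'
#' Generates a deterministic (per seed) two-contig genome carrying
#' `n_mirnas` hairpin genes: at least 20% inside the deletion interval,
#' ~40% elsewhere on the deletion contig, and the remainder on a second
#' contig. Each hairpin (60-110 nt) carries one or two annotated mature
#' sub-intervals (20-23 nt, kept >= 3 nt from the hairpin ends so every
#' tolerated isomiR offset stays inside the hairpin). The genome sequence
#' at each locus equals the hairpin (reverse complement on minus strand),
#' and the non-hairpin space is tiled with categorized gene features used
#' by the background-read simulator and read categorization.
#'
#' @param config A [SimulationConfig-class].
#' @return A [ToyReference-class] object. Writes nothing.
#' @examples
#' ref <- buildToyReference(simulationConfig(n_mirnas = 10, seed = 3))
#' ref
#' @export
buildToyReference <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  set.seed(config@seed)
  di <- config@deletion_interval
  del_contig <- as.character(seqnames(di))
  other_contig <- if (del_contig == "chr1") "chr2" else "chr1"
  if (start(di) < 1L)
    stop("configuration error: deletion_interval outside contig bounds")

  n <- config@n_mirnas
  n_in <- max(1L, ceiling(0.2 * n))
  n_out <- ceiling(0.4 * n)
  n_other <- n - n_in - n_out
  if (n_other < 0L) { n_out <- n - n_in; n_other <- 0L }

  hp_len <- sample(60:110, n, replace = TRUE)
  hp_id <- sprintf("toy-mir-%03d", seq_len(n))
  hp_seq <- vapply(hp_len, randomDna, character(1))

  # mature sub-intervals: 5p arm always; 3p arm for ~30% of hairpins
  mat <- do.call(rbind, lapply(seq_len(n), function(i) {
    len <- hp_len[i]
    two <- runif(1) < 0.3
    l5 <- sample(20:23, 1L)
    out <- data.frame(hairpin = hp_id[i], start = 4L, end = 4L + l5 - 1L,
                      mature_id = if (two) paste0(sub("mir", "miR", hp_id[i]), "-5p")
                                  else sub("mir", "miR", hp_id[i]))
    if (two) {
      l3 <- sample(20:23, 1L)
      out <- rbind(out, data.frame(
        hairpin = hp_id[i], start = len - 3L - l3 + 1L, end = len - 3L,
        mature_id = paste0(sub("mir", "miR", hp_id[i]), "-3p")))
    }
    out
  }))

  # genomic placement
  pad <- 2000L
  zone_out <- c(end(di) + pad, end(di) + pad + max(1L, n_out) * 200L + pad)
  del_len <- zone_out[2L] + pad
  other_len <- max(1L, n_other) * 200L + 2L * pad
  if (end(di) > del_len)
    stop("configuration error: deletion_interval outside contig bounds")

  idx_in <- seq_len(n_in)
  idx_out <- seq_len(n_out) + n_in
  idx_other <- setdiff(seq_len(n), c(idx_in, idx_out))
  starts <- numeric(n); contig <- character(n)
  starts[idx_in] <- placeHairpins(start(di), end(di), hp_len[idx_in])
  contig[idx_in] <- del_contig
  if (n_out) {
    starts[idx_out] <- placeHairpins(zone_out[1L], zone_out[2L], hp_len[idx_out])
    contig[idx_out] <- del_contig
  }
  if (n_other) {
    starts[idx_other] <- placeHairpins(pad, other_len - pad, hp_len[idx_other])
    contig[idx_other] <- other_contig
  }
  strand <- ifelse(runif(n) < 0.7, "+", "-")

  genome <- setNames(c(randomDna(del_len), randomDna(other_len)),
                     c(del_contig, other_contig))
  # splice hairpin sequences into the genome at their loci
  for (i in seq_len(n)) {
    s <- if (strand[i] == "+") hp_seq[i] else
      as.character(Biostrings::reverseComplement(DNAStringSet(hp_seq[i])))
    substr(genome[contig[i]], starts[i], starts[i] + hp_len[i] - 1L) <- s
  }

  loci <- GRanges(contig, IRanges(starts, width = hp_len), strand = strand,
                  hairpin_id = hp_id)
  gene_features <- tileGeneFeatures(
    setNames(c(del_len, other_len), c(del_contig, other_contig)), loci)

  ref <- new("ToyReference",
             genome = DNAStringSet(genome),
             hairpins = setNames(DNAStringSet(hp_seq), hp_id),
             matures = GRanges(mat$hairpin, IRanges(mat$start, mat$end),
                               strand = "+", mature_id = mat$mature_id),
             loci = loci,
             gene_features = gene_features)
  validObject(ref)
  ref
}

# Tile non-hairpin genome space with categorized features (150-500 bp),
# leaving a 20 bp margin around each hairpin locus.
tileGeneFeatures <- function(contig_len, loci) {
  cats <- c("protein_coding", "lincRNA", "snoRNA", "tRNA", "rRNA",
            "intergenic")
  wts <- c(0.35, 0.15, 0.1, 0.1, 0.1, 0.2)
  free <- GenomicRanges::setdiff(
    GRanges(names(contig_len), IRanges(1L, contig_len)),
    GenomicRanges::reduce(GenomicRanges::resize(
      loci, width(loci) + 40L, fix = "center"), ignore.strand = TRUE),
    ignore.strand = TRUE)
  out <- list()
  for (i in seq_along(free)) {
    a <- start(free)[i]; b <- end(free)[i]
    pos <- a
    while (b - pos >= 150L) {
      len <- sample(150:500, 1L)
      len <- min(len, b - pos + 1L)
      out[[length(out) + 1L]] <- data.frame(
        contig = as.character(seqnames(free))[i], start = pos,
        end = pos + len - 1L,
        strand = sample(c("+", "-"), 1L),
        category = sample(cats, 1L, prob = wts))
      pos <- pos + len + sample(20:80, 1L)
    }
  }
  out <- do.call(rbind, out)
  GRanges(out$contig, IRanges(out$start, out$end), strand = out$strand,
          category = out$category)
}

#' Genomic coordinates of mature miRNAs
#'
#' Projects each mature's hairpin-relative interval onto the genome through
#' its hairpin locus (strand aware).
#'
#' @param ref A [ToyReference-class].
#' @return `GRanges` with a `mature_id` metadata column.
#' @export
matureLoci <- function(ref) {
  loc <- ref@loci
  key <- setNames(seq_along(loc), mcols(loc)$hairpin_id)
  i <- key[as.character(seqnames(ref@matures))]
  hp_start <- start(loc)[i]; hp_end <- end(loc)[i]
  st <- as.character(strand(loc))[i]
  gs <- ifelse(st == "+", hp_start + start(ref@matures) - 1L,
               hp_end - end(ref@matures) + 1L)
  ge <- ifelse(st == "+", hp_start + end(ref@matures) - 1L,
               hp_end - start(ref@matures) + 1L)
  GRanges(as.character(seqnames(loc))[i], IRanges(gs, ge), strand = st,
          mature_id = mcols(ref@matures)$mature_id)
}

#' Simulate the true mature-miRNA count matrix
#'
#' Counts follow a negative binomial: `count_ij ~ NB(mean = s_j * mu_i *
#' fold_ij, dispersion alpha_i)`, where `fold_ij` equals the deletion
#' effect for deletion-region matures in case samples (times any extra
#' per-mature fold), and 1 otherwise. `alpha = 0` reduces to Poisson.
#' Deletion-region membership is by mature-locus midpoint. Baseline means
#' are log-normal except in the deletion region, where `in_region_high`
#' matures are drawn from `in_region_high_range` and the remainder sit at
#' `in_region_low_mean` (see vignette).
#'
#' @param ref A [ToyReference-class].
#' @param config A [SimulationConfig-class].
#' @param means Optional named numeric vector overriding baseline means.
#' @return A [SmallRnaTruth-class] object.
#' @export
simulateCounts <- function(ref, config, means = NULL) {
  stopifnot(is(ref, "ToyReference"), is(config, "SimulationConfig"))
  if (any(config@dispersion < 0)) stop("dispersion must be >= 0")
  set.seed(config@seed + 1L)
  ml <- matureLoci(ref)
  ids <- mcols(ml)$mature_id
  G <- length(ids)
  mid <- (start(ml) + end(ml)) / 2
  di <- config@deletion_interval
  in_region <- as.character(seqnames(ml)) == as.character(seqnames(di)) &
    mid >= start(di) & mid <= end(di)

  if (is.null(means)) {
    means <- setNames(
      rlnorm(G, config@mean_log_location, config@mean_log_scale), ids)
    ir <- which(in_region)
    if (length(ir)) {
      nh <- min(config@in_region_high, length(ir))
      hi <- ir[sample.int(length(ir), nh)]
      means[hi] <- runif(nh, config@in_region_high_range[1L],
                         config@in_region_high_range[2L])
      means[setdiff(ir, hi)] <- config@in_region_low_mean
    }
  } else {
    means <- means[ids]
    if (anyNA(means)) stop("means must be named by mature id")
  }

  fold <- setNames(rep(1, G), ids)
  fold[in_region] <- config@deletion_effect
  if (length(config@extra_de)) {
    ex <- intersect(names(config@extra_de), ids)
    fold[ex] <- fold[ex] * config@extra_de[ex]
  }

  n <- config@n_control + config@n_case
  groups <- rep(c("control", "case"), c(config@n_control, config@n_case))
  samples <- sprintf("%s_%02d", ifelse(groups == "control", "ctrl", "case"),
                     c(seq_len(config@n_control), seq_len(config@n_case)))
  sf <- setNames(rlnorm(n, 0, config@libsize_sigma), samples)

  disp <- config@dispersion
  alpha <- if (length(disp) == 2L) disp[2L] / pmax(means, 1e-8) + disp[1L]
           else rep(disp, G)

  counts <- matrix(0L, G, n, dimnames = list(ids, samples))
  for (j in seq_len(n)) {
    mu <- sf[j] * means * (if (groups[j] == "case") fold else rep(1, G))
    counts[, j] <- as.integer(ifelse(alpha == 0, rpois(G, mu),
                                     rnbinom(G, mu = mu, size = 1 / alpha)))
  }
  new("SmallRnaTruth", counts = counts, fold = fold,
      true_de = ids[fold != 1], means = means, size_factors = sf,
      groups = groups)
}

#' Synthesize per-sample FASTQ files from true counts
#'
#' Each miRNA read is its mature hairpin sub-sequence extended/shortened by
#' 5' and 3' offsets drawn independently from `isomir_offset_probs`, with
#' per-base substitution errors, then the 3' adapter appended (except for
#' an `adapterless_fraction` of reads), padded with `A` to `read_length`
#' and truncated to `read_length`. Background reads are 15-35 nt fragments
#' drawn uniformly from non-miRNA gene features. Qualities are a constant
#' `I`; read order is shuffled within each sample. Output is deterministic
#' for a given config (byte-identical FASTQ).
#'
#' @param truth A [SmallRnaTruth-class] from [simulateCounts()].
#' @param ref The [ToyReference-class] used to simulate `truth`.
#' @param config The same [SimulationConfig-class].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `fastq` (named file paths) and
#'   `provenance` (one row per synthesized read: sample, read id, origin
#'   type and id, offsets, error count, adapterless flag).
#' @export
synthesizeReads <- function(truth, ref, config, dir) {
  stopifnot(is(truth, "SmallRnaTruth"))
  set.seed(config@seed + 2L)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  L <- config@read_length
  offs <- as.integer(names(config@isomir_offset_probs))
  opr <- config@isomir_offset_probs

  hp_chr <- setNames(as.character(ref@hairpins), names(ref@hairpins))
  mat_hp <- setNames(as.character(seqnames(ref@matures)),
                     mcols(ref@matures)$mature_id)
  mat_start <- setNames(start(ref@matures), mcols(ref@matures)$mature_id)
  mat_end <- setNames(end(ref@matures), mcols(ref@matures)$mature_id)
  if (L < 15L) stop("read_length shorter than the shortest insert")

  feats <- ref@gene_features[width(ref@gene_features) >= 35L]
  gen_chr <- setNames(as.character(ref@genome), names(ref@genome))

  files <- character(0)
  prov <- list()
  for (j in seq_len(ncol(truth@counts))) {
    smp <- colnames(truth@counts)[j]
    cnt <- truth@counts[, j]
    n_mi <- sum(cnt)
    mat_ids <- rep(rownames(truth@counts), cnt)
    off5 <- sample(offs, n_mi, replace = TRUE, prob = opr)
    off3 <- sample(offs, n_mi, replace = TRUE, prob = opr)
    ins <- substr(hp_chr[mat_hp[mat_ids]],
                  mat_start[mat_ids] + off5, mat_end[mat_ids] + off3)

    bg_frac <- config@background_fraction
    n_bg <- if (bg_frac > 0) round(bg_frac / (1 - bg_frac) * n_mi) else 0L
    if (n_bg > 0L) {
      fi <- sample.int(length(feats), n_bg, replace = TRUE)
      blen <- sample(15:35, n_bg, replace = TRUE)
      bstart <- start(feats)[fi] +
        floor(runif(n_bg) * (width(feats)[fi] - blen + 1L))
      bseq <- substr(gen_chr[as.character(seqnames(feats))[fi]],
                     bstart, bstart + blen - 1L)
      minus <- as.character(strand(feats))[fi] == "-"
      if (any(minus))
        bseq[minus] <- as.character(
          Biostrings::reverseComplement(DNAStringSet(bseq[minus])))
    } else bseq <- character(0)

    seqs <- c(ins, bseq)
    origin_type <- rep(c("miRNA", "background"), c(n_mi, n_bg))
    origin_id <- c(mat_ids,
                   if (n_bg) mcols(feats)$category[fi] else character(0))
    o5 <- c(off5, rep(NA_integer_, n_bg))
    o3 <- c(off3, rep(NA_integer_, n_bg))
    ntot <- length(seqs)
    if (ntot && L < min(nchar(seqs)))
      stop("read_length shorter than the shortest insert")

    nerr <- rbinom(ntot, nchar(seqs), config@error_rate)
    for (k in which(nerr > 0L)) {
      pos <- sample.int(nchar(seqs[k]), nerr[k])
      for (p in pos) {
        cur <- substr(seqs[k], p, p)
        substr(seqs[k], p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
      }
    }
    adapterless <- runif(ntot) < config@adapterless_fraction
    reads <- paste0(seqs, ifelse(adapterless, "", config@adapter))
    short <- nchar(reads) < L
    reads[short] <- paste0(reads[short],
                           strrep("A", L - nchar(reads[short])))
    reads <- substr(reads, 1L, L)

    ord <- sample.int(ntot)
    ids <- sprintf("%s_r%07d", smp, seq_len(ntot))
    fq <- file.path(dir, paste0(smp, ".fastq"))
    writeLines(paste0("@", ids, "\n", reads[ord], "\n+\n",
                      strrep("I", nchar(reads[ord]))), fq)
    files[smp] <- fq
    prov[[smp]] <- data.frame(
      sample = smp, read = ids,
      origin_type = origin_type[ord], origin_id = origin_id[ord],
      off5 = o5[ord], off3 = o3[ord], n_errors = nerr[ord],
      adapterless = adapterless[ord])
  }
  invisible(list(fastq = files, provenance = do.call(rbind, prov)))
}

#' Write a toy reference to FASTA and GFF3 files
#'
#' Writes `genome.fa`, `hairpins.fa`, `hairpin_annotation.gff3` (mature
#' intervals on hairpin coordinates) and `genome_annotation.gff3` (hairpin
#' loci as `miRNA_primary_transcript` plus categorized gene features);
#' GFF3 coordinates are 1-based inclusive with the strand column honored.
#'
#' @param ref A [ToyReference-class].
#' @param dir Output directory.
#' @return Invisibly, the named vector of written paths.
#' @export
writeToyReference <- function(ref, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             hairpins = file.path(dir, "hairpins.fa"),
             hairpin_gff = file.path(dir, "hairpin_annotation.gff3"),
             genome_gff = file.path(dir, "genome_annotation.gff3"))
  Biostrings::writeXStringSet(ref@genome, paths["genome"])
  Biostrings::writeXStringSet(ref@hairpins, paths["hairpins"])

  m <- ref@matures
  mg <- GRanges(seqnames(m), IRanges(start(m), end(m)), strand = strand(m),
                type = "miRNA", ID = mcols(m)$mature_id)
  rtracklayer::export(mg, paths["hairpin_gff"], format = "gff3")
  loc <- ref@loci; gf <- ref@gene_features
  gg <- c(GRanges(seqnames(loc), IRanges(start(loc), end(loc)),
                  strand = strand(loc), type = "miRNA_primary_transcript",
                  ID = mcols(loc)$hairpin_id),
          GRanges(seqnames(gf), IRanges(start(gf), end(gf)),
                  strand = strand(gf), type = mcols(gf)$category,
                  ID = paste0("feature-", seq_along(gf))))
  rtracklayer::export(gg, paths["genome_gff"], format = "gff3")
  invisible(paths)
}

#' Read a toy reference written by [writeToyReference()]
#'
#' @param dir Directory containing the four reference files.
#' @return A [ToyReference-class].
#' @export
readToyReference <- function(dir) {
  genome <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  hairpins <- Biostrings::readDNAStringSet(file.path(dir, "hairpins.fa"))
  names(genome) <- sub("\\s.*$", "", names(genome))
  names(hairpins) <- sub("\\s.*$", "", names(hairpins))
  hg <- rtracklayer::import(file.path(dir, "hairpin_annotation.gff3"))
  gg <- rtracklayer::import(file.path(dir, "genome_annotation.gff3"))
  hp <- gg[mcols(gg)$type == "miRNA_primary_transcript"]
  gf <- gg[mcols(gg)$type != "miRNA_primary_transcript"]
  new("ToyReference", genome = genome, hairpins = hairpins,
      matures = GRanges(seqnames(hg), IRanges(start(hg), end(hg)),
                        strand = "+", mature_id = mcols(hg)$ID),
      loci = GRanges(seqnames(hp), IRanges(start(hp), end(hp)),
                     strand = strand(hp), hairpin_id = mcols(hp)$ID),
      gene_features = GRanges(seqnames(gf), IRanges(start(gf), end(gf)),
                              strand = strand(gf),
                              category = as.character(mcols(gf)$type)))
}
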