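# Independent brute-force oracles used to cross-check the implementation.

suppressMessages({
  library(GenomicRanges)
  library(Biostrings)
  library(SummarizedExperiment)
})

# Naive Hamming-distance scan at every offset of every target.
naiveHammingScan <- function(read, targets, max_mismatches = 1L,
                             both_strands = FALSE) {
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  pats <- list("+" = read)
  if (both_strands) pats[["-"]] <- rc(read)
  w <- nchar(read)
  out <- list()
  for (st in names(pats)) {
    p <- strsplit(pats[[st]], "")[[1]]
    for (t in names(targets)) {
      tch <- strsplit(targets[[t]], "")[[1]]
      L <- length(tch)
      if (w > L) next
      for (s in seq_len(L - w + 1L)) {
        mm <- sum(p != tch[s:(s + w - 1L)])
        if (mm <= max_mismatches)
          out[[length(out) + 1L]] <- data.frame(
            target = t, start = s, end = s + w - 1L, strand = st,
            mismatches = mm, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(target = character(), start = integer(),
                      end = integer(), strand = character(),
                      mismatches = integer(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# Step-up BH by its definition.
bruteForceBH <- function(p, m = length(p)) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  for (i in seq_len(n)) {
    vals <- vapply(i:n, function(j) m * p[o[j]] / j, 0)
    adj[o[i]] <- min(1, min(vals))
  }
  adj
}

# One- and two-sided Fisher p by full enumeration with choose().
enumFisher <- function(a, b, c, d) {
  n1 <- a + b; K <- a + c; N <- a + b + c + d
  lo <- max(0L, n1 - (N - K)); hi <- min(n1, K)
  probs <- vapply(lo:hi, function(x)
    choose(K, x) * choose(N - K, n1 - x) / choose(N, n1), 0)
  xs <- lo:hi
  p_one <- sum(probs[xs >= a])
  p_obs <- probs[match(a, xs)]
  p_two <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  list(p_one_sided = min(p_one, 1), p_two_sided = min(p_two, 1))
}

# Textbook pooled-variance two-sample t-test.
textbookTTest <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(statistic = t, df = df, p_two_sided = 2 * pt(-abs(t), df))
}

# Brute-force leftmost adapter-trim position: try every cut point and test
# the adapter prefix (possibly running off the read) directly.
bruteTrim <- function(read, adapter, min_overlap = 6L,
                      max_mismatch_rate = 0.1) {
  n <- nchar(read)
  for (pos in seq_len(max(n - min_overlap + 1L, 0L))) {
    ov <- min(n - pos + 1L, nchar(adapter))
    if (ov < min_overlap) break
    mm <- sum(strsplit(substr(read, pos, pos + ov - 1L), "")[[1]] !=
              strsplit(substr(adapter, 1L, ov), "")[[1]])
    if (mm / ov <= max_mismatch_rate)
      return(list(sequence = substr(read, 1L, pos - 1L),
                  adapter_found = TRUE))
  }
  list(sequence = read, adapter_found = FALSE)
}

# Shared fixture configs -----------------------------------------------------

pointMassOffsets <- c("-3" = 0, "-2" = 0, "-1" = 0, "0" = 1,
                      "1" = 0, "2" = 0, "3" = 0)

cleanConfig <- function(n_mirnas = 20L, n_control = 3L, n_case = 3L,
                        seed = 5L, ...) {
  simulationConfig(n_mirnas = n_mirnas, n_control = n_control,
                   n_case = n_case, seed = seed, error_rate = 0,
                   background_fraction = 0, adapterless_fraction = 0,
                   isomir_offset_probs = pointMassOffsets,
                   mean_log_location = log(50), ...)
}

# Tiny deterministic GO annotation for enrichment tests.
toyAnnotation <- function() {
  genes <- sprintf("g%02d", 1:20)
  data.frame(
    gene = c(genes[1:4], genes[3:10], genes[11:16]),
    term = rep(c("GO:1", "GO:2", "GO:3"), c(4, 8, 6)),
    term_name = rep(c("synapse organization", "axon guidance",
                      "lipid metabolic process"), c(4, 8, 6)),
    stringsAsFactors = FALSE)
}
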