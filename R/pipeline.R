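#' Read a flat key=value run-configuration file
#'
#' One `key = value` pair per line; blank lines and `#` comments ignored.
#' Values are kept as strings and coerced by [runPipeline()].
#'
#' @param path Config file path.
#' @return Named list of strings.
#' @export
readRunConfig <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- lengths(kv) != 3L
  if (any(bad)) stop("cannot parse config line(s): ",
                     paste(lines[bad], collapse = "; "))
  setNames(lapply(kv, function(x) trimws(x[3L])),
           vapply(kv, function(x) trimws(x[2L]), ""))
}

pipelineDefaults <- function() list(
  out_dir = "mirna22q_run", seed = 1L,
  n_mirnas = 300L, n_control = 9L, n_case = 7L,
  deletion_interval = "chr22:10001-40000", deletion_effect = 0.5,
  error_rate = 0.005, background_fraction = 0.15,
  adapterless_fraction = 0.07, read_length = 50L,
  adapter = "TGGAATTCTCGGGTGCCAAGG",
  p_cut = 0.01, fold_cut = 1.5, fdr_cut = 0.05, rpm_threshold = 1,
  oc_cut = 0.5, exclude_samples = "",
  targets_tsv = "", go_annotation_tsv = "", term_groups_tsv = "",
  ct_tsv = "")

coercePipelineConfig <- function(cfg) {
  num <- c("seed", "n_mirnas", "n_control", "n_case", "deletion_effect",
           "error_rate", "background_fraction", "adapterless_fraction",
           "read_length", "p_cut", "fold_cut", "fdr_cut", "rpm_threshold",
           "oc_cut")
  for (k in intersect(num, names(cfg))) cfg[[k]] <- as.numeric(cfg[[k]])
  if (cfg$p_cut <= 0 || cfg$p_cut > 1 || cfg$fdr_cut <= 0 ||
      cfg$fdr_cut > 1 || cfg$fold_cut < 1)
    stop("config validation error: need 0 < p_cut, fdr_cut <= 1 and ",
         "fold_cut >= 1")
  cfg
}

pipeLog <- function(cfg, stage, msg) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg)
  message(line)
  cat(line, "\n", file = file.path(cfg$out_dir, "run.log"), append = TRUE)
}

writeTsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Generate a toy regulator-target table with GO annotation
#'
#' Creates a synthetic gene universe, per-miRNA target sets with mixed
#' confidence labels, a gene-to-GO-term annotation whose term names mix
#' neural and non-neural vocabulary, and a term-to-functional-group map —
#' the inputs the network stage expects when no real prediction tables
#' are supplied.
#'
#' @param mirnas Character vector of miRNA ids.
#' @param seed Integer seed.
#' @param n_genes,n_terms Universe and term counts.
#' @return list with `targets`, `annotation` and `groups` data.frames.
#' @export
simulateTargetAnnotation <- function(mirnas, seed = 1L, n_genes = 400L,
                                     n_terms = 24L) {
  set.seed(seed)
  genes <- sprintf("GENE%04d", seq_len(n_genes))
  stems <- c("neuron differentiation", "synapse organization",
             "axon guidance", "dendrite morphogenesis",
             "brain development", "neurotransmitter secretion",
             "glial cell development", "forebrain neurogenesis",
             "lipid metabolic process", "cell cycle",
             "DNA repair", "immune response")
  nm <- paste(rep_len(stems, n_terms),
              rep(seq_len(ceiling(n_terms / length(stems))),
                  each = length(stems))[seq_len(n_terms)])
  terms <- sprintf("GO:%07d", seq_len(n_terms))
  annotation <- do.call(rbind, lapply(seq_len(n_terms), function(i)
    data.frame(gene = sample(genes, sample(15:40, 1L)), term = terms[i],
               term_name = nm[i], stringsAsFactors = FALSE)))
  targets <- do.call(rbind, lapply(mirnas, function(m) {
    # bias targets toward a few terms so enrichment is detectable
    fav <- sample(terms, 2L)
    pool <- unique(c(annotation$gene[annotation$term %in% fav],
                     sample(genes, 40L)))
    data.frame(mirna_id = m, gene = sample(pool, min(45L, length(pool))),
               confidence = sample(c("experimentally_validated",
                                     "high_confidence", "moderate"),
                                   min(45L, length(pool)), replace = TRUE,
                                   prob = c(0.15, 0.6, 0.25)),
               source = "toy", stringsAsFactors = FALSE)
  }))
  groups <- data.frame(term = terms,
                       group = ifelse(grepl("neuro|synap|axon|dendrit|brain|glial",
                                            nm, ignore.case = TRUE),
                                      "neural function", "other"),
                       stringsAsFactors = FALSE)
  list(targets = targets, annotation = annotation, groups = groups)
}

#' Generate a toy qPCR Ct table consistent with simulated folds
#'
#' Produces triplicate Ct values for a handful of assays plus the two
#' small-RNA normalizers, with case-group Ct shifted by -log2(fold).
#'
#' @param assays Named numeric vector of true case-vs-control folds per
#'   target assay.
#' @param n_control,n_case Samples per group.
#' @param seed Integer seed.
#' @param sd_ct Per-well Ct standard deviation.
#' @return Long-format data.frame (sample, group, assay, replicate, ct).
#' @export
simulateQpcrTable <- function(assays, n_control = 6L, n_case = 6L,
                              seed = 1L, sd_ct = 0.15) {
  set.seed(seed)
  samples <- c(sprintf("ctrl_%02d", seq_len(n_control)),
               sprintf("case_%02d", seq_len(n_case)))
  groups <- rep(c("control", "case"), c(n_control, n_case))
  all_assays <- c(assays, SNORD48 = 1, U6 = 1)
  base <- setNames(runif(length(all_assays), 18, 26), names(all_assays))
  out <- list()
  for (i in seq_along(samples)) for (a in names(all_assays)) {
    shift <- if (groups[i] == "case" && !a %in% c("SNORD48", "U6"))
      -log2(all_assays[[a]]) else 0
    out[[length(out) + 1L]] <- data.frame(
      sample = samples[i], group = groups[i], assay = a,
      replicate = 1:3, ct = round(base[[a]] + shift + rnorm(3, 0, sd_ct), 3),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Run the analysis pipeline
#'
#' Single entry point wiring the stages: `simulate` (toy reference, truth
#' and FASTQ), `quantify` (FASTQ to counts), `de` (differential
#' expression), `region` (deletion enrichment), `network` (GO overlap
#' network), `qpcr` (relative-expression report) or `all`. Stages consume
#' the TSV/FASTA/FASTQ/GFF3 artifacts of earlier stages from `out_dir`;
#' under `all`, a stage whose outputs already exist is skipped, so partial
#' pipelines resume from existing intermediates. Given the same config and
#' seed, outputs are byte-identical across runs.
#'
#' @param subcommand One of `simulate`, `quantify`, `de`, `region`,
#'   `network`, `qpcr`, `all`.
#' @param config Named list of overrides (highest precedence).
#' @param config_file Optional flat key=value config file.
#' @return Invisibly, a named list of the artifacts produced.
#' @export
runPipeline <- function(subcommand = c("all", "simulate", "quantify", "de",
                                       "region", "network", "qpcr"),
                        config = list(), config_file = NULL) {
  subcommand <- match.arg(subcommand)
  cfg <- pipelineDefaults()
  if (!is.null(config_file)) {
    fromfile <- readRunConfig(config_file)
    cfg[names(fromfile)] <- fromfile
  }
  cfg[names(config)] <- config
  cfg <- coercePipelineConfig(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  arts <- list()
  stages <- if (subcommand == "all")
    c("simulate", "quantify", "de", "region", "network", "qpcr")
  else subcommand
  for (st in stages) {
    done <- stageOutputs(cfg, st)
    if (subcommand == "all" && length(done) && all(file.exists(done))) {
      pipeLog(cfg, st, "outputs exist; resuming from intermediates")
      arts[[st]] <- done
      next
    }
    arts[[st]] <- switch(st,
      simulate = stageSimulate(cfg),
      quantify = stageQuantify(cfg),
      de = stageDe(cfg),
      region = stageRegion(cfg),
      network = stageNetwork(cfg),
      qpcr = stageQpcr(cfg))
  }
  invisible(arts)
}

stageOutputs <- function(cfg, stage) {
  o <- cfg$out_dir
  switch(stage,
    simulate = file.path(o, c("reference/genome.fa", "sample_sheet.tsv",
                              "truth_counts.tsv", "mature_loci.tsv")),
    quantify = file.path(o, c("counts.tsv", "read_fates.tsv")),
    de = file.path(o, c("de_results.tsv", "volcano.tsv")),
    region = file.path(o, "region_report.tsv"),
    network = file.path(o, c("network.sif", "network.graphml")),
    qpcr = file.path(o, "qpcr_report.tsv"))
}

stageConfigObject <- function(cfg) {
  simulationConfig(
    n_control = cfg$n_control, n_case = cfg$n_case,
    n_mirnas = cfg$n_mirnas, deletion_interval = cfg$deletion_interval,
    deletion_effect = cfg$deletion_effect, error_rate = cfg$error_rate,
    background_fraction = cfg$background_fraction,
    adapter = cfg$adapter,
    adapterless_fraction = cfg$adapterless_fraction,
    read_length = as.integer(cfg$read_length), seed = as.integer(cfg$seed))
}

stageSimulate <- function(cfg) {
  sc <- stageConfigObject(cfg)
  ref <- buildToyReference(sc)
  pipeLog(cfg, "simulate", sprintf("reference: %d hairpins, %d matures",
                                   length(ref@hairpins),
                                   length(ref@matures)))
  writeToyReference(ref, file.path(cfg$out_dir, "reference"))
  truth <- simulateCounts(ref, sc)
  rs <- synthesizeReads(truth, ref, sc, file.path(cfg$out_dir, "fastq"))
  pipeLog(cfg, "simulate", sprintf("%d reads in %d samples",
                                   nrow(rs$provenance),
                                   length(rs$fastq)))
  writeTsv(data.frame(mature_id = rownames(truth@counts), truth@counts,
                      check.names = FALSE),
           file.path(cfg$out_dir, "truth_counts.tsv"))
  writeTsv(data.frame(sample = colnames(truth@counts),
                      group = truth@groups,
                      subject = colnames(truth@counts), clone = 1L),
           file.path(cfg$out_dir, "sample_sheet.tsv"))
  ml <- matureLoci(ref)
  writeTsv(data.frame(mature_id = mcols(ml)$mature_id,
                      contig = as.character(seqnames(ml)),
                      start = start(ml), end = end(ml),
                      strand = as.character(strand(ml))),
           file.path(cfg$out_dir, "mature_loci.tsv"))
  writeTsv(rs$provenance, file.path(cfg$out_dir, "truth_provenance.tsv"))
  stageOutputs(cfg, "simulate")
}

stageQuantify <- function(cfg) {
  refdir <- file.path(cfg$out_dir, "reference")
  fqdir <- file.path(cfg$out_dir, "fastq")
  if (!dir.exists(refdir) || !dir.exists(fqdir))
    stop("missing inputs for quantify: run the simulate stage first or ",
         "provide ", refdir, " and ", fqdir)
  fq <- list.files(fqdir, "\\.fastq$", full.names = TRUE)
  names(fq) <- sub("\\.fastq$", "", basename(fq))
  sheet <- read.table(file.path(cfg$out_dir, "sample_sheet.tsv"),
                      header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  fq <- fq[sheet$sample]
  mce <- quantifyReads(fq, readToyReference(refdir),
                       groups = sheet$group, adapter = cfg$adapter)
  pipeLog(cfg, "quantify", sprintf(
    "%d reads processed; %d assigned to miRNAs",
    sum(readFates(mce)$total), sum(assignedTotals(mce))))
  writeTsv(data.frame(mature_id = rownames(mce),
                      SummarizedExperiment::assay(mce, "counts"),
                      check.names = FALSE),
           file.path(cfg$out_dir, "counts.tsv"))
  writeTsv(readFates(mce), file.path(cfg$out_dir, "read_fates.tsv"))
  stageOutputs(cfg, "quantify")
}

readCountsTsv <- function(path) {
  x <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                  stringsAsFactors = FALSE)
  m <- as.matrix(x[, -1L, drop = FALSE])
  rownames(m) <- x[[1L]]
  m
}

stageDe <- function(cfg) {
  cpath <- file.path(cfg$out_dir, "counts.tsv")
  if (!file.exists(cpath))
    stop("missing ", cpath, ": run the quantify stage first")
  counts <- readCountsTsv(cpath)
  sheet <- read.table(file.path(cfg$out_dir, "sample_sheet.tsv"),
                      header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  excl <- trimws(strsplit(cfg$exclude_samples, ",")[[1]])
  excl <- excl[nzchar(excl)]
  res <- runDifferentialExpression(
    counts, groups = setNames(sheet$group, sheet$sample)[colnames(counts)],
    exclude_samples = excl, p_cut = cfg$p_cut, fold_cut = cfg$fold_cut,
    fdr_cut = cfg$fdr_cut)
  s <- attr(res, "summary")
  pipeLog(cfg, "de", sprintf(
    "%d tested (%d samples excluded); %d nominal (%d down, %d up), %d genome-wide",
    nrow(res), length(excl), s["total"], s["down"], s["up"],
    s["genomewide"]))
  writeTsv(data.frame(mature_id = rownames(res), res, check.names = FALSE),
           file.path(cfg$out_dir, "de_results.tsv"))
  writeTsv(data.frame(mature_id = rownames(res), log2FC = res$log2FC,
                      neg_log10_p = -log10(pmax(res$pvalue, 1e-300))),
           file.path(cfg$out_dir, "volcano.tsv"))
  stageOutputs(cfg, "de")
}

stageRegion <- function(cfg) {
  dpath <- file.path(cfg$out_dir, "de_results.tsv")
  lpath <- file.path(cfg$out_dir, "mature_loci.tsv")
  if (!file.exists(dpath) || !file.exists(lpath))
    stop("missing DE results or mature loci; run earlier stages first")
  de <- read.table(dpath, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  loci <- read.table(lpath, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
  counts <- readCountsTsv(file.path(cfg$out_dir, "counts.tsv"))
  rt <- testRegionEnrichment(
    de$mature_id[de$nominal], loci, cfg$deletion_interval,
    counts = counts, assigned_totals = colSums(counts),
    rpm_threshold = cfg$rpm_threshold)
  pipeLog(cfg, "region", sprintf(
    "table [%d %d; %d %d], one-sided p = %.3g",
    rt$table[1, 1], rt$table[1, 2], rt$table[2, 1], rt$table[2, 2],
    rt$p_one_sided))
  writeTsv(data.frame(in_region_de = rt$table[1, 1],
                      in_region_not_de = rt$table[1, 2],
                      out_region_de = rt$table[2, 1],
                      out_region_not_de = rt$table[2, 2],
                      p_one_sided = rt$p_one_sided,
                      p_two_sided = rt$p_two_sided,
                      rpm_threshold = cfg$rpm_threshold),
           file.path(cfg$out_dir, "region_report.tsv"))
  stageOutputs(cfg, "region")
}

stageNetwork <- function(cfg) {
  dpath <- file.path(cfg$out_dir, "de_results.tsv")
  if (!file.exists(dpath))
    stop("missing ", dpath, ": run the de stage first")
  de <- read.table(dpath, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  de <- de[de$nominal, ]
  if (!nrow(de)) {
    pipeLog(cfg, "network", "no nominally DE miRNAs; writing empty network")
    net <- buildTermNetwork(emptyEnrichment(), list(), character())
    exportNetwork(net, sif = file.path(cfg$out_dir, "network.sif"),
                  graphml = file.path(cfg$out_dir, "network.graphml"))
    return(stageOutputs(cfg, "network"))
  }
  if (nzchar(cfg$targets_tsv)) {
    targets <- read.table(cfg$targets_tsv, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
    annotation <- read.table(cfg$go_annotation_tsv, header = TRUE,
                             sep = "\t", stringsAsFactors = FALSE)
    groups <- if (nzchar(cfg$term_groups_tsv))
      read.table(cfg$term_groups_tsv, header = TRUE, sep = "\t",
                 stringsAsFactors = FALSE) else NULL
  } else {
    toy <- simulateTargetAnnotation(de$mature_id, seed = cfg$seed)
    targets <- toy$targets; annotation <- toy$annotation
    groups <- toy$groups
  }
  targets <- filterTargets(targets)
  res <- do.call(rbind, lapply(unique(de$mature_id), function(m)
    enrichTerms(targets$gene[targets$mirna_id == m], annotation,
                mirna_id = m)))
  if (is.null(res)) res <- emptyEnrichment()
  sel <- selectBrainTerms(res)
  term_targets <- lapply(split(annotation$gene, annotation$term),
                         function(g) intersect(unique(targets$gene), g))
  dirs <- setNames(ifelse(de$log2FC > 0, "down", "up"), de$mature_id)
  net <- buildTermNetwork(sel, term_targets, dirs, oc_cut = cfg$oc_cut,
                          group_map = groups)
  exportNetwork(net, sif = file.path(cfg$out_dir, "network.sif"),
                graphml = file.path(cfg$out_dir, "network.graphml"))
  pipeLog(cfg, "network", sprintf("%d nodes, %d edges",
                                  igraph::vcount(net), igraph::ecount(net)))
  stageOutputs(cfg, "network")
}

stageQpcr <- function(cfg) {
  if (nzchar(cfg$ct_tsv)) {
    ct <- read.table(cfg$ct_tsv, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
  } else {
    dpath <- file.path(cfg$out_dir, "de_results.tsv")
    if (!file.exists(dpath))
      stop("missing ", dpath, " and no ct_tsv given; run the de stage or ",
           "provide Ct measurements")
    de <- read.table(dpath, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    de <- de[de$nominal, ]
    pick <- head(de$mature_id, 4L)
    folds <- setNames(2^-de$log2FC[match(pick, de$mature_id)], pick)
    ct <- simulateQpcrTable(folds, seed = cfg$seed)
  }
  targets <- setdiff(unique(ct$assay), c("SNORD48", "U6"))
  rep_rows <- do.call(rbind, lapply(targets, function(a) {
    sub <- ct[ct$assay %in% c(a, "SNORD48", "U6"), ]
    r <- deltaDeltaCt(sub, a, c("SNORD48", "U6"))
    data.frame(assay = a, fold = r$fold, ddct = r$ddct,
               t = r$ttest$statistic, df = r$ttest$df,
               p_two_sided = r$ttest$p_two_sided,
               p_one_sided = r$ttest$p_one_sided)
  }))
  pipeLog(cfg, "qpcr", sprintf("%d assays analyzed", nrow(rep_rows)))
  writeTsv(rep_rows, file.path(cfg$out_dir, "qpcr_report.tsv"))
  stageOutputs(cfg, "qpcr")
}
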