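#' @importFrom igraph graph_from_data_frame make_empty_graph write_graph
#'   read_graph vertex_attr edge_attr V E as_data_frame vcount ecount
NULL

#' Filter a regulator-target table by prediction confidence
#'
#' Keeps only target records whose confidence is in `allowed` (by default
#' experimentally validated or high-confidence predictions) and
#' de-duplicates (miRNA, gene) pairs.
#'
#' @param table data.frame with columns `mirna_id`, `gene`, `confidence`
#'   (and optionally `source`).
#' @param allowed Character vector of allowed confidence labels.
#' @return The filtered, de-duplicated table.
#' @export
filterTargets <- function(table,
                          allowed = c("experimentally_validated",
                                      "high_confidence")) {
  vocab <- c("experimentally_validated", "high_confidence", "moderate")
  bad <- setdiff(unique(table$confidence), vocab)
  if (length(bad))
    stop("unknown confidence label(s): ", paste(bad, collapse = ", "))
  out <- table[table$confidence %in% allowed, , drop = FALSE]
  out[!duplicated(out[, c("mirna_id", "gene")]), , drop = FALSE]
}

#' Hypergeometric GO-term enrichment of one miRNA's targets
#'
#' For each term with at least one target gene, the right-tailed
#' hypergeometric p-value of drawing `k` term genes in `n` targets from a
#' universe of `N` genes containing `K` term genes; the EASE variant
#' recomputes the same tail with the overlap decremented by one (`k - 1`
#' against unchanged `n`, `K`, `N`), a deliberately conservative score.
#' Results with `p_fisher < p_cut` are retained.
#'
#' @param targets Character vector of one miRNA's target genes.
#' @param annotation data.frame with columns `gene` and `term` (and
#'   optionally `term_name`).
#' @param universe Gene universe; defaults to all annotated genes. Must
#'   contain every annotated gene.
#' @param p_cut Retention cutoff on the Fisher p-value (default 0.05).
#' @param mirna_id Optional id copied into the result.
#' @return data.frame with `mirna_id`, `term`, `term_name`, `k`, `n`, `K`,
#'   `N`, `p_fisher`, `p_ease`, ordered by `p_fisher`.
#' @export
enrichTerms <- function(targets, annotation, universe = NULL, p_cut = 0.05,
                        mirna_id = NA_character_) {
  if (is.null(universe)) universe <- unique(annotation$gene)
  if (!all(annotation$gene %in% universe))
    stop("universe must contain every annotated gene")
  targets <- intersect(unique(targets), universe)
  n <- length(targets)
  N <- length(universe)
  out <- lapply(split(annotation, annotation$term), function(ann) {
    genes <- unique(ann$gene)
    K <- length(genes)
    k <- length(intersect(targets, genes))
    if (k < 1L) return(NULL)
    data.frame(mirna_id = mirna_id, term = ann$term[1L],
               term_name = if ("term_name" %in% names(ann))
                 ann$term_name[1L] else ann$term[1L],
               k = k, n = n, K = K, N = N,
               p_fisher = phyper(k - 1L, K, N - K, n, lower.tail = FALSE),
               p_ease = phyper(k - 2L, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(emptyEnrichment())
  out <- out[out$p_fisher < p_cut, , drop = FALSE]
  rownames(out) <- NULL
  out[order(out$p_fisher), , drop = FALSE]
}

emptyEnrichment <- function() {
  data.frame(mirna_id = character(), term = character(),
             term_name = character(), k = integer(), n = integer(),
             K = integer(), N = integer(), p_fisher = numeric(),
             p_ease = numeric(), stringsAsFactors = FALSE)
}

#' Select neuron/brain-related GO terms by keyword
#'
#' Case-insensitive substring match of any keyword against the term name.
#'
#' @param results Enrichment results (from [enrichTerms()]).
#' @param keywords Keyword vector; the defaults cover neuronal, synaptic
#'   and glial vocabulary.
#' @return The matching subset of `results`.
#' @export
selectBrainTerms <- function(results,
                             keywords = c("neuro", "neuron", "brain",
                                          "synap", "axon", "dendrit",
                                          "glia")) {
  if (!length(keywords)) stop("keyword list must not be empty")
  pat <- paste(keywords, collapse = "|")
  results[grepl(pat, results$term_name, ignore.case = TRUE), ,
          drop = FALSE]
}

#' Overlap coefficient of two gene sets
#'
#' `|A intersect B| / min(|A|, |B|)`; both sets must be non-empty.
#'
#' @param a,b Character vectors (sets).
#' @return Scalar in `[0, 1]`.
#' @examples
#' overlapCoefficient(c("a", "b", "c"), c("b", "c", "d", "e"))  # 2/3
#' @export
overlapCoefficient <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (!length(a) || !length(b))
    stop("overlap coefficient undefined for empty sets")
  length(intersect(a, b)) / min(length(a), length(b))
}

#' Build the GO-term / miRNA network
#'
#' Nodes are the selected GO terms (sized by the number of predicted miRNA
#' targets they contain, optionally labeled with a functional group) and
#' the miRNAs with at least one retained enrichment. A grey term-term edge
#' connects two terms iff the overlap coefficient of their target sets is
#' strictly greater than `oc_cut`; a miRNA-term edge records each retained
#' enrichment.
#'
#' @param results Selected enrichment results (rows with `mirna_id`,
#'   `term`, `term_name`).
#' @param term_targets Named list: per term, the character vector of
#'   predicted miRNA target genes in the term. Every term in `results`
#'   must be present; empty target sets are skipped with a warning.
#' @param mirna_directions Named character vector ("up"/"down") per miRNA.
#' @param oc_cut Overlap-coefficient cutoff (strict, default 0.5).
#' @param group_map Optional two-column data.frame (`term`, `group`)
#'   assigning functional groups to terms.
#' @return An `igraph` graph; node attributes `kind` ("term"/"mirna"),
#'   `label`, `size`, `group`, `direction`; edge attributes `relation`
#'   ("term_term"/"mirna_term") and `weight` (overlap coefficient for
#'   term-term edges).
#' @export
buildTermNetwork <- function(results, term_targets, mirna_directions,
                             oc_cut = 0.5, group_map = NULL) {
  terms <- unique(results$term)
  missing <- setdiff(terms, names(term_targets))
  if (length(missing))
    stop("no target set for term(s): ", paste(missing, collapse = ", "))
  mirnas <- unique(results$mirna_id)

  term_name <- setNames(results$term_name, results$term)[terms]
  grp <- rep(NA_character_, length(terms))
  if (!is.null(group_map))
    grp <- group_map$group[match(terms, group_map$term)]
  nodes <- data.frame(
    name = c(terms, mirnas),
    kind = rep(c("term", "mirna"), c(length(terms), length(mirnas))),
    label = c(unname(term_name), mirnas),
    size = c(vapply(term_targets[terms],
                    function(x) length(unique(x)), 0L),
             rep(NA_integer_, length(mirnas))),
    group = c(grp, rep(NA_character_, length(mirnas))),
    direction = c(rep(NA_character_, length(terms)),
                  unname(mirna_directions[mirnas])),
    stringsAsFactors = FALSE)

  edges <- list()
  if (length(terms) > 1L) {
    for (i in seq_len(length(terms) - 1L)) for (j in (i + 1L):length(terms)) {
      A <- term_targets[[terms[i]]]; B <- term_targets[[terms[j]]]
      if (!length(A) || !length(B)) {
        warning("empty target set; skipping pair ", terms[i], " / ",
                terms[j])
        next
      }
      oc <- overlapCoefficient(A, B)
      if (oc > oc_cut)
        edges[[length(edges) + 1L]] <- data.frame(
          from = terms[i], to = terms[j], relation = "term_term",
          weight = oc, stringsAsFactors = FALSE)
    }
  }
  if (nrow(results))
    edges[[length(edges) + 1L]] <- data.frame(
      from = results$mirna_id, to = results$term,
      relation = "mirna_term", weight = NA_real_,
      stringsAsFactors = FALSE)
  edges <- if (length(edges)) do.call(rbind, edges)
           else data.frame(from = character(), to = character(),
                           relation = character(), weight = numeric())
  graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
}

#' Export a term network to SIF and GraphML
#'
#' SIF lines are `source <TAB> relation <TAB> target`, canonically sorted
#' so identical inputs give byte-identical files; GraphML carries all node
#' and edge attributes and can be re-read into an isomorphic graph (e.g.
#' for Cytoscape-style visualization tools).
#'
#' @param network An `igraph` graph from [buildTermNetwork()].
#' @param sif,graphml Output paths (either may be `NULL` to skip).
#' @return Invisibly, the written paths.
#' @export
exportNetwork <- function(network, sif = NULL, graphml = NULL) {
  paths <- character()
  if (!is.null(sif)) {
    e <- igraph::as_data_frame(network, what = "edges")
    lines <- if (nrow(e))
      sort(paste(e$from, e$relation, e$to, sep = "\t")) else character()
    ok <- tryCatch({ writeLines(lines, sif); TRUE },
                   error = function(err)
                     stop("cannot write SIF to ", sif, ": ",
                          conditionMessage(err)))
    paths["sif"] <- sif
  }
  if (!is.null(graphml)) {
    tryCatch(write_graph(network, graphml, format = "graphml"),
             error = function(err)
               stop("cannot write GraphML to ", graphml, ": ",
                    conditionMessage(err)))
    paths["graphml"] <- graphml
  }
  invisible(paths)
}

#' Read a GraphML network written by [exportNetwork()]
#'
#' @param path GraphML file path.
#' @return An `igraph` graph.
#' @export
readNetwork <- function(path) {
  read_graph(path, format = "graphml")
}
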