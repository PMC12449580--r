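# Small in-code fixtures shared across test files.

toy_be <- function(counts, treatment = NULL, substrate = NULL,
                   timepoint = NULL, taxonomy = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) rownames(counts) <- sprintf("f%02d", seq_len(nrow(counts)))
  if (is.null(colnames(counts))) colnames(counts) <- sprintf("s%02d", seq_len(ncol(counts)))
  md <- NULL
  if (!is.null(treatment)) {
    md <- data.frame(sample_id = colnames(counts), treatment = treatment,
                     substrate = substrate %||% "seaweed",
                     timepoint = timepoint %||% "exp1",
                     panel = "panel_01", bottle = "bottle_01")
  }
  BiofilmExperiment(counts, sampleData = md, taxonomy = taxonomy)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A deterministic AssociationNetwork from an edge list (weights +/-1).
toy_network <- function(edges, n_nodes = max(unlist(edges[, 1:2])), weights = NULL) {
  ids <- sprintf("n%02d", seq_len(n_nodes))
  if (is.null(weights)) weights <- rep(1, nrow(edges))
  e <- data.frame(from = ids[pmin(edges[, 1], edges[, 2])],
                  to = ids[pmax(edges[, 1], edges[, 2])],
                  weight = weights, sign = ifelse(weights > 0, "+", "-"),
                  stability = NA_real_, stringsAsFactors = FALSE)
  e <- e[order(e$from, e$to), ]
  rownames(e) <- NULL
  methods::new("AssociationNetwork",
    nodes = data.frame(feature_id = ids, domain_class = NA_character_,
                       mean_rel_abundance = NA_real_, stringsAsFactors = FALSE),
    edges = e, lambdaSelected = numeric(), instability = numeric(),
    params = list())
}

# The hand-scored 10-node, 2-module graph used for Zi/Pi checks.
zipi_toy <- function() {
  edges <- rbind(c(1, 2), c(1, 3), c(1, 4), c(1, 5), c(2, 3),
                 c(6, 7), c(6, 8), c(6, 9), c(6, 10), c(7, 8), c(9, 10),
                 c(5, 6), c(3, 7))
  net <- toy_network(edges, 10)
  part <- methods::new("ModulePartition",
    membership = stats::setNames(c(rep(1L, 5), rep(2L, 5)), sprintf("n%02d", 1:10)),
    Q = oracle_modularity(as.matrix(igraph::as_adjacency_matrix(
      asIgraph(net, weighted = FALSE), sparse = FALSE)), c(rep(1, 5), rep(2, 5))),
    method = "fixed", seed = 0L)
  list(net = net, part = part)
}
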