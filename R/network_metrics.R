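# All topological metrics are computed on the unweighted graph; edge weights
# enter only through mean_abs_weight and the sign fields.

.unweighted_igraph <- function(net) {
  if (methods::is(net, "AssociationNetwork")) asIgraph(net, weighted = FALSE)
  else net
}

.net_adjacency <- function(net) {
  g <- .unweighted_igraph(net)
  as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
}

#' Basic node- and network-level metrics
#'
#' Mean degree `2E / N`, edge density `2E / (N (N - 1))`, global
#' transitivity (3 x triangles / connected triples; 0 when there are no
#' connected triples), mean betweenness on unweighted shortest paths,
#' fraction of negative edges and mean absolute edge weight (both 0 for an
#' edgeless graph).
#'
#' @param net an [AssociationNetwork-class].
#' @param transitivity_type `"global"` (default) or `"localaverage"`.
#' @return named numeric vector.
#' @export
basicMetrics <- function(net, transitivity_type = c("global", "localaverage")) {
  transitivity_type <- match.arg(transitivity_type)
  g <- .unweighted_igraph(net)
  n <- igraph::vcount(g); e <- igraph::ecount(g)
  stopifnot(n >= 1)
  tr <- igraph::transitivity(g, type = transitivity_type, isolates = "zero")
  if (is.nan(tr)) tr <- 0
  ed <- net@edges
  c(n_nodes = n, n_edges = e,
    edge_density = if (n > 1) 2 * e / (n * (n - 1)) else 0,
    mean_degree = 2 * e / n,
    mean_betweenness = mean(igraph::betweenness(g, directed = FALSE, weights = NA)),
    transitivity = tr,
    prop_negative_edges = if (e > 0) mean(ed$sign == "-") else 0,
    mean_abs_weight = if (e > 0) mean(abs(ed$weight)) else 0)
}

#' Natural connectivity
#'
#' Spectral robustness measure: `log(mean(exp(lambda_i)))` over the
#' eigenvalues of the unweighted adjacency matrix, evaluated with the
#' usual log-sum-exp stabilisation. Zero for an edgeless graph; strictly
#' increasing under edge addition.
#'
#' @param net an [AssociationNetwork-class], igraph graph, or adjacency
#'   matrix.
#' @return scalar.
#' @export
naturalConnectivity <- function(net) {
  a <- if (is.matrix(net)) net else .net_adjacency(net)
  if (nrow(a) == 0) stop("need at least 1 node")
  ev <- eigen(a, symmetric = TRUE, only.values = TRUE)$values
  m <- max(ev)
  m + log(mean(exp(ev - m)))
}

.modularity_q <- function(adj, membership) {
  e <- sum(adj) / 2
  if (e == 0) return(0)
  deg <- rowSums(adj)
  q <- 0
  for (m in unique(membership)) {
    idx <- membership == m
    e_mm <- sum(adj[idx, idx]) / 2 / e
    a_m <- sum(deg[idx]) / (2 * e)
    q <- q + e_mm - a_m^2
  }
  q
}

#' Detect modules by modularity maximization
#'
#' Greedy multilevel (Louvain) optimization of Newman-Girvan modularity on
#' the unweighted graph, restarted `n_restarts` times over random vertex
#' orders; the best partition is kept. Deterministic under a fixed seed.
#' An edgeless graph yields a single module with `Q = 0` by convention.
#'
#' @param net an [AssociationNetwork-class] or igraph graph.
#' @param n_restarts number of restarts (default 10).
#' @param seed RNG seed.
#' @return a [ModulePartition-class].
#' @export
detectModules <- function(net, n_restarts = 10, seed = 1L) {
  g <- .unweighted_igraph(net)
  n <- igraph::vcount(g)
  nodes <- igraph::V(g)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(n))
  if (igraph::ecount(g) == 0) {
    memb <- stats::setNames(rep(1L, n), nodes)
    return(methods::new("ModulePartition", membership = memb, Q = 0,
                        method = "louvain_multirestart", seed = as.integer(seed)))
  }
  adj <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  set.seed(as.integer(seed))
  best_q <- -Inf; best <- NULL
  consider <- function(memb) {
    q <- .modularity_q(adj, memb)
    if (q > best_q + 1e-12) { best_q <<- q; best <<- memb }
  }
  # deterministic greedy candidates complement the randomized restarts
  consider(as.integer(igraph::membership(igraph::cluster_fast_greedy(g))))
  try(consider(as.integer(igraph::membership(igraph::cluster_leading_eigen(g)))),
      silent = TRUE)
  for (r in seq_len(n_restarts)) {
    perm <- sample(n)
    gp <- igraph::permute(g, perm)
    cl <- igraph::cluster_louvain(gp)
    # igraph::permute sends old vertex i to new vertex perm[i], so the
    # community of old vertex i is the new membership at position perm[i]
    consider(as.integer(igraph::membership(cl))[perm])
  }
  best <- as.integer(factor(best, levels = unique(best)))
  methods::new("ModulePartition",
               membership = stats::setNames(best, nodes), Q = best_q,
               method = "louvain_multirestart", seed = as.integer(seed))
}

#' Within-module degree (Zi) and participation coefficient (Pi)
#'
#' For each node i with degree `k_i` and `k_im` edges into module m:
#' `Zi = (k_i,own - mean(k,own)) / sd(k,own)` over the members of i's own
#' module (0 when the sd is 0), and `Pi = 1 - sum_m (k_im / k_i)^2`
#' (0 for isolated nodes). Topological roles: *network hub* when
#' `Zi >= z_thresh` and `Pi >= p_thresh`; *module hub* when only the Zi
#' condition holds; *connector* when only the Pi condition holds;
#' *peripheral* otherwise.
#'
#' @param net an [AssociationNetwork-class] or igraph graph.
#' @param partition a [ModulePartition-class] covering all nodes (default:
#'   computed with [detectModules()]).
#' @param z_thresh within-module connectivity threshold (default 2.5).
#' @param p_thresh participation threshold (default 0.62).
#' @param seed passed to [detectModules()] when `partition` is missing.
#' @return data.frame (one row per node): `node`, `degree`, `betweenness`,
#'   `module`, `Zi`, `Pi`, `role`.
#' @export
ziPi <- function(net, partition = NULL, z_thresh = 2.5, p_thresh = 0.62,
                 seed = 1L) {
  g <- .unweighted_igraph(net)
  if (is.null(partition)) partition <- detectModules(net, seed = seed)
  adj <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  nodes <- igraph::V(g)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(nrow(adj)))
  memb <- partition@membership[nodes]
  if (anyNA(memb)) stop("partition does not cover all nodes")
  mods <- sort(unique(memb))
  # k[i, m]: edges from node i into module m
  k_im <- vapply(mods, function(m) rowSums(adj[, memb == m, drop = FALSE]),
                 numeric(nrow(adj)))
  if (is.null(dim(k_im))) k_im <- matrix(k_im, nrow = nrow(adj))
  deg <- rowSums(adj)
  k_own <- k_im[cbind(seq_along(memb), match(memb, mods))]
  zi <- numeric(length(memb))
  for (m in mods) {
    idx <- which(memb == m)
    mu <- mean(k_own[idx]); sdv <- stats::sd(k_own[idx])
    zi[idx] <- if (length(idx) < 2 || is.na(sdv) || sdv == 0) 0
               else (k_own[idx] - mu) / sdv
  }
  pi <- ifelse(deg > 0, 1 - rowSums((k_im / pmax(deg, 1))^2), 0)
  role <- ifelse(zi >= z_thresh & pi >= p_thresh, "network_hub",
          ifelse(zi >= z_thresh, "module_hub",
          ifelse(pi >= p_thresh, "connector", "peripheral")))
  data.frame(node = nodes, degree = deg,
             betweenness = igraph::betweenness(g, directed = FALSE, weights = NA),
             module = unname(memb), Zi = zi, Pi = pi, role = role,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fixed-order network metric profile
#'
#' Assembles the network-level metrics into the fixed-order named vector
#' used for between-network comparison: `n_nodes`, `n_edges`,
#' `edge_density`, `mean_degree`, `mean_betweenness`, `transitivity`,
#' `modularity_Q`, `natural_connectivity`, `prop_negative_edges`,
#' `mean_abs_weight`.
#'
#' @param net an [AssociationNetwork-class].
#' @param n_restarts,seed module-detection controls.
#' @return named numeric vector (fixed field order, all finite).
#' @export
networkProfile <- function(net, n_restarts = 10, seed = 1L) {
  bm <- basicMetrics(net)
  q <- if (nrow(net@edges) == 0) 0 else detectModules(net, n_restarts, seed)@Q
  out <- c(bm["n_nodes"], bm["n_edges"], bm["edge_density"], bm["mean_degree"],
           bm["mean_betweenness"], bm["transitivity"], modularity_Q = q,
           natural_connectivity = naturalConnectivity(net),
           bm["prop_negative_edges"], bm["mean_abs_weight"])
  stopifnot(all(is.finite(out)))
  out
}
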