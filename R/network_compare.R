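.profile_matrix <- function(profiles) {
  if (is.matrix(profiles)) m <- profiles
  else {
    fields <- names(profiles[[1]])
    if (any(!vapply(profiles, function(p) identical(names(p), fields), logical(1))))
      stop("all profiles must have identical field sets in identical order")
    m <- do.call(rbind, profiles)
    rownames(m) <- names(profiles)
  }
  if (any(!is.finite(m))) stop("non-finite profile entries")
  m
}

.standardize_profiles <- function(m, standardize) {
  if (standardize == "none") return(m)
  sds <- apply(m, 2, stats::sd)
  zero <- sds == 0
  if (any(zero)) {
    warning("dropping zero-variance metric(s): ",
            paste(colnames(m)[zero], collapse = ", "))
    m <- m[, !zero, drop = FALSE]
    sds <- sds[!zero]
  }
  scale(m, center = TRUE, scale = sds)
}

#' Euclidean distances between network profiles
#'
#' Each metric is z-scored across networks (zero-variance metrics dropped
#' with a warning; raw metrics have incomparable scales, so the
#' unstandardized distance would be dominated by node/edge counts), then
#' pairwise Euclidean distances are computed. `standardize = "none"` gives
#' the plain Euclidean distance.
#'
#' @param profiles named list of [networkProfile()] vectors (or a networks x
#'   metrics matrix).
#' @param standardize `"zscore"` (default) or `"none"`.
#' @return symmetric matrix of distances with network labels as dimnames.
#' @export
profileDistance <- function(profiles, standardize = c("zscore", "none")) {
  standardize <- match.arg(standardize)
  m <- .profile_matrix(profiles)
  if (nrow(m) < 2) stop("need at least 2 profiles")
  s <- .standardize_profiles(m, standardize)
  if (ncol(s) == 0)   # all metrics constant: the profiles are identical
    return(matrix(0, nrow(m), nrow(m), dimnames = list(rownames(m), rownames(m))))
  as.matrix(stats::dist(s, method = "euclidean"))
}

#' PCA of network profiles
#'
#' Principal components of the (z-scored) profile matrix. In full rank the
#' pairwise Euclidean distances between scores equal [profileDistance()]
#' exactly.
#'
#' @inheritParams profileDistance
#' @return list: `coordinates` (networks x components), `eigenvalues`
#'   (variances of the components, descending), `proportion_explained`.
#' @export
profilePCA <- function(profiles, standardize = c("zscore", "none")) {
  standardize <- match.arg(standardize)
  m <- .profile_matrix(profiles)
  if (nrow(m) < 3) stop("need at least 3 profiles for PCA")
  s <- .standardize_profiles(m, standardize)
  if (ncol(s) == 0)   # all metrics constant: identical profiles, zero scores
    return(list(coordinates = matrix(0, nrow(m), 1,
                                     dimnames = list(rownames(m), "PC1")),
                eigenvalues = 0, proportion_explained = numeric(0)))
  pc <- stats::prcomp(s, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  list(coordinates = pc$x, eigenvalues = ev,
       proportion_explained = if (sum(ev) > 0) ev / sum(ev) else ev)
}

#' Shared nodes and edges between two networks
#'
#' Shared nodes are the intersection of the feature IDs; shared edges are
#' the unordered feature pairs present in both networks *with the same
#' association sign* (an association flipping sign across networks is not
#' treated as shared). Symmetric in its arguments.
#'
#' @param g1,g2 [AssociationNetwork-class] objects over a common feature
#'   namespace.
#' @return list: `shared_nodes` (character), `shared_edges`
#'   (data.frame(from, to, sign)), `n_nodes`, `n_edges`.
#' @export
sharedStructure <- function(g1, g2) {
  nodes <- intersect(g1@nodes$feature_id, g2@nodes$feature_id)
  key <- function(e) paste(e$from, e$to, e$sign, sep = "\r")
  e1 <- g1@edges; e2 <- g2@edges
  shared_keys <- intersect(key(e1), key(e2))
  se <- e1[key(e1) %in% shared_keys, c("from", "to", "sign")]
  rownames(se) <- NULL
  list(shared_nodes = sort(nodes), shared_edges = se,
       n_nodes = length(nodes), n_edges = nrow(se))
}

#' Score an inferred network against a ground-truth edge set
#'
#' Precision, recall and F1 of the inferred (undirected, unsigned) edge set
#' against [truthEdgeSet()] pairs.
#'
#' @param net an [AssociationNetwork-class].
#' @param truth data.frame(from, to) of true edges (feature IDs).
#' @return named numeric: `tp`, `fp`, `fn`, `precision`, `recall`, `f1`.
#' @export
edgeRecovery <- function(net, truth) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  est <- unique(key(net@edges$from, net@edges$to))
  tru <- unique(key(truth$from, truth$to))
  tp <- length(intersect(est, tru))
  fp <- length(setdiff(est, tru))
  fn <- length(setdiff(tru, est))
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  c(tp = tp, fp = fp, fn = fn, precision = prec, recall = rec, f1 = f1)
}
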