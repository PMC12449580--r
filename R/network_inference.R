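#' Whole-microbial-community (WMC) feature filter
#'
#' Keeps features with at least `min_total_reads` reads in total across the
#' table and mean relative abundance at least `min_mean_rel_abund`
#' (default 0.25% — the abundance floor at which host networks stabilise);
#' everything else is excluded before network inference. A per-sample
#' minimum variant is available via `per_sample = TRUE`, which requires the
#' feature's *maximum* per-sample relative abundance to reach the threshold.
#'
#' @param x a `BiofilmExperiment`.
#' @param min_total_reads inclusive total-read threshold (default 3).
#' @param min_mean_rel_abund inclusive mean relative-abundance threshold
#'   (default 0.0025).
#' @param per_sample interpret the abundance threshold against the maximum
#'   per-sample relative abundance instead of the mean.
#' @return the filtered `BiofilmExperiment`.
#' @export
wmcFilter <- function(x, min_total_reads = 3, min_mean_rel_abund = 0.0025,
                      per_sample = FALSE) {
  m <- counts(x)
  if (nrow(m) == 0) stop("empty table")
  ra <- relAbundance(m)
  ab <- if (per_sample) apply(ra, 1, max) else rowMeans(ra)
  keep <- rowSums(m) >= min_total_reads & ab >= min_mean_rel_abund
  if (sum(keep) < 3)
    stop("wmcFilter: fewer than 3 features survive; no meaningful network")
  x[keep, ]
}

#' Centered log-ratio transform
#'
#' `clr(x)_ij = log((x_ij + pseudocount) / g_i)` with `g_i` the geometric
#' mean of sample i's pseudocounted abundances. Every row of the result
#' sums to zero. The default unit pseudocount is the standard convention
#' for integer count tables; real-valued tables without zeros may use
#' `pseudocount = 0`.
#'
#' @param x `BiofilmExperiment` or features x samples matrix.
#' @param pseudocount non-negative value added before taking logs; must be
#'   positive when zeros are present.
#' @return samples x features matrix (regression orientation) with
#'   attribute `"pseudocount"`; rows sum to 0 (tolerance 1e-9).
#' @export
clrTransform <- function(x, pseudocount = 1) {
  m <- if (methods::is(x, "BiofilmExperiment")) counts(x) else as.matrix(x)
  if (any(m < 0)) stop("clrTransform: negative entries")
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  if (pseudocount == 0 && any(m == 0))
    stop("pseudocount must be > 0 when zeros are present")
  z <- t(m) + pseudocount            # samples x features
  lz <- log(z)
  out <- lz - rowMeans(lz)
  attr(out, "pseudocount") <- pseudocount
  out
}

.standardize_cols <- function(x) {
  n <- nrow(x)
  ctr <- sweep(x, 2, colMeans(x))
  sds <- sqrt(colSums(ctr^2) / n)     # population sd, glmnet's convention
  sds[sds == 0] <- 1
  sweep(ctr, 2, sds, "/")
}

#' Largest useful penalty and the default penalty path
#'
#' `lambdaMax` is the smallest penalty at which every neighborhood
#' regression is empty: the maximum absolute cross-product between distinct
#' standardized columns divided by the sample count. `lambdaPath` returns
#' `n_lambda` log-spaced values from `lambdaMax` down to
#' `min_ratio * lambdaMax` (descending).
#'
#' @param clr samples x features matrix from [clrTransform()].
#' @param n_lambda path length (default 30).
#' @param min_ratio smallest penalty as a fraction of `lambdaMax`.
#' @return `lambdaMax`: a scalar; `lambdaPath`: descending numeric vector.
#' @export
lambdaMax <- function(clr) {
  s <- .standardize_cols(clr)
  cp <- abs(crossprod(s)) / nrow(s)
  diag(cp) <- 0
  max(cp)
}

#' @rdname lambdaMax
#' @export
lambdaPath <- function(clr, n_lambda = 30, min_ratio = 0.01) {
  lmax <- lambdaMax(clr)
  exp(seq(log(lmax), log(min_ratio * lmax), length.out = n_lambda))
}

# Neighborhood regressions over a whole penalty path.
# Returns a p x p x L array B with B[j, k, l] = coefficient of feature k in
# the lasso regression of feature j at penalty lambda[l]; B[j, j, ] = 0.
.mb_path <- function(clr, lambda) {
  s <- .standardize_cols(clr)
  p <- ncol(s)
  lam <- sort(lambda, decreasing = TRUE)
  b <- array(0, dim = c(p, p, length(lam)))
  for (j in seq_len(p)) {
    fit <- glmnet::glmnet(s[, -j, drop = FALSE], s[, j], family = "gaussian",
                          lambda = lam, standardize = FALSE, intercept = FALSE,
                          thresh = 1e-10)
    cf <- as.matrix(fit$beta)
    # glmnet may stop early on a degenerate path; align by lambda
    li <- match(round(lam, 12), round(fit$lambda, 12))
    ok <- !is.na(li)
    b[j, -j, which(ok)] <- cf[, li[ok], drop = FALSE]
  }
  attr(b, "lambda") <- lam
  b
}

#' Lasso neighborhood selection at a single penalty
#'
#' For each feature j, an L1-penalized least-squares regression of its
#' (column-standardized) CLR abundances on all other features at penalty
#' `lambda` (glmnet objective `RSS / (2n) + lambda * |beta|_1`).
#'
#' @param clr samples x features matrix from [clrTransform()].
#' @param lambda positive penalty.
#' @return p x p coefficient matrix `B` with `B[j, k]` the coefficient of
#'   feature k in j's regression and zero diagonal.
#' @export
neighborhoodLasso <- function(clr, lambda) {
  if (nrow(clr) < 4) stop("need at least 4 samples")
  if (any(!is.finite(clr))) stop("non-finite values in input")
  stopifnot(lambda > 0)
  b <- .mb_path(clr, lambda)[, , 1]
  dimnames(b) <- list(colnames(clr), colnames(clr))
  b
}

.adjacency_from_b <- function(b, rule) {
  nz <- b != 0
  if (rule == "or") (nz | t(nz)) else (nz & t(nz))
}

#' StARS stability selection
#'
#' Stability Approach to Regularization Selection: the neighborhood-selection
#' graph is re-estimated on `n_subsamples` random subsamples (without
#' replacement, size `min(floor(10 sqrt(n)), floor(0.8 n))` by default)
#' across the penalty path. Each edge's instability at a penalty is
#' `2 theta (1 - theta)` with `theta` its cross-subsample selection
#' frequency; the total instability `D(lambda)` is the mean over all feature
#' pairs. `D` is monotonized from the sparsest (largest-penalty) end and the
#' smallest penalty (densest graph) with monotonized instability at most
#' `beta_threshold` is selected. If no penalty qualifies the sparsest one is
#' returned with a warning.
#'
#' @param clr samples x features CLR matrix.
#' @param lambda_path descending penalties (default [lambdaPath()]).
#' @param n_subsamples number of subsamples (default 20).
#' @param subsample_size subsample size; default the StARS recommendation.
#' @param beta_threshold instability threshold (default 0.05).
#' @param rule `"or"` or `"and"` symmetrization for the subsample graphs.
#' @param seed RNG seed.
#' @return list: `lambda_selected`, `index`, `instability` (monotonized, per
#'   penalty), `instability_raw`, `edge_stability` (p x p matrix of
#'   selection frequencies at the selected penalty), `lambda_path`,
#'   `params`.
#' @export
starsSelect <- function(clr, lambda_path = lambdaPath(clr), n_subsamples = 20,
                        subsample_size = NULL, beta_threshold = 0.05,
                        rule = c("or", "and"), seed = 1L) {
  rule <- match.arg(rule)
  n <- nrow(clr); p <- ncol(clr)
  if (length(lambda_path) < 2) stop("lambda_path must have length >= 2")
  lam <- sort(lambda_path, decreasing = TRUE)
  if (is.null(subsample_size))
    subsample_size <- min(floor(10 * sqrt(n)), floor(0.8 * n))
  if (subsample_size < 4) stop("subsample size must be >= 4")
  set.seed(as.integer(seed))
  freq <- array(0, dim = c(p, p, length(lam)))
  for (s in seq_len(n_subsamples)) {
    idx <- sample(n, subsample_size)
    b <- .mb_path(clr[idx, , drop = FALSE], lam)
    for (l in seq_along(lam))
      freq[, , l] <- freq[, , l] + .adjacency_from_b(b[, , l], rule)
  }
  theta <- freq / n_subsamples
  ut <- upper.tri(matrix(0, p, p))
  d_raw <- vapply(seq_along(lam), function(l) {
    inst <- 2 * theta[, , l] * (1 - theta[, , l])
    mean(inst[ut])
  }, numeric(1))
  d_mono <- cummax(d_raw)
  ok <- which(d_mono <= beta_threshold)
  if (length(ok)) {
    sel <- max(ok)
  } else {
    warning("no penalty reaches instability <= ", beta_threshold,
            "; selecting the sparsest")
    sel <- 1L
  }
  stab <- theta[, , sel]
  dimnames(stab) <- list(colnames(clr), colnames(clr))
  list(lambda_selected = lam[sel], index = sel, instability = d_mono,
       instability_raw = d_raw, edge_stability = stab, lambda_path = lam,
       params = list(n_subsamples = n_subsamples, subsample_size = subsample_size,
                     beta_threshold = beta_threshold, rule = rule, seed = seed))
}

#' Symmetrize neighborhood coefficients into a signed network
#'
#' An edge (j, k) exists when `B[j, k] != 0` or (`rule = "and"`: and)
#' `B[k, j] != 0`. Its weight is the mean of the two coefficients; when the
#' two are non-zero with opposite signs the larger-magnitude coefficient is
#' taken instead and the conflict counted (`params$sign_conflicts`).
#'
#' @param b p x p coefficient matrix with feature IDs as dimnames.
#' @param rule `"or"` (default) or `"and"`.
#' @param node_data optional data.frame(feature_id, domain_class,
#'   mean_rel_abundance).
#' @param stability optional p x p edge-selection-frequency matrix.
#' @param lambda_selected,instability provenance scalars.
#' @param params extra provenance list entries.
#' @return an [AssociationNetwork-class].
#' @export
buildNetwork <- function(b, rule = c("or", "and"), node_data = NULL,
                         stability = NULL, lambda_selected = numeric(),
                         instability = numeric(), params = list()) {
  rule <- match.arg(rule)
  ids <- rownames(b)
  if (is.null(ids)) ids <- .feature_ids(nrow(b))
  adj <- .adjacency_from_b(b, rule)
  conflicts <- 0L
  edges <- data.frame(from = character(), to = character(), weight = numeric(),
                      sign = character(), stability = numeric(),
                      stringsAsFactors = FALSE)
  idx <- which(upper.tri(adj) & adj, arr.ind = TRUE)
  if (nrow(idx)) {
    w <- numeric(nrow(idx))
    for (r in seq_len(nrow(idx))) {
      j <- idx[r, 1]; k <- idx[r, 2]
      bjk <- b[j, k]; bkj <- b[k, j]
      if (bjk != 0 && bkj != 0 && sign(bjk) != sign(bkj)) {
        conflicts <- conflicts + 1L
        w[r] <- if (abs(bjk) >= abs(bkj)) bjk else bkj
      } else w[r] <- (bjk + bkj) / 2
    }
    keep <- w != 0
    idx <- idx[keep, , drop = FALSE]; w <- w[keep]
    edges <- data.frame(from = ids[idx[, 1]], to = ids[idx[, 2]], weight = w,
                        sign = ifelse(w > 0, "+", "-"),
                        stability = if (is.null(stability)) NA_real_
                                    else stability[idx],
                        stringsAsFactors = FALSE)
  }
  if (is.null(node_data))
    node_data <- data.frame(feature_id = ids, domain_class = NA_character_,
                            mean_rel_abundance = NA_real_, stringsAsFactors = FALSE)
  params$rule <- rule
  params$sign_conflicts <- conflicts
  methods::new("AssociationNetwork", nodes = node_data, edges = edges,
               lambdaSelected = lambda_selected, instability = instability,
               params = params)
}

#' Infer a sparse association network from a count table
#'
#' The full compositionally robust inference chain on one sample group:
#' CLR transform (unit pseudocount), lasso neighborhood selection over a
#' log-spaced penalty path, StARS stability selection of the penalty, a
#' final fit on the full data at the selected penalty, and symmetrization
#' into a signed weighted network. Bit-reproducible under a fixed seed.
#'
#' @param x a `BiofilmExperiment`, already subset to the samples of one
#'   group and filtered ([wmcFilter()] or a core subset).
#' @param pseudocount CLR pseudocount (default 1).
#' @param n_lambda,lambda_min_ratio penalty path controls.
#' @param n_subsamples,subsample_size,beta_threshold,rule,seed see
#'   [starsSelect()].
#' @return an [AssociationNetwork-class] with node metadata (domain class,
#'   mean relative abundance) filled from the table.
#' @export
inferNetwork <- function(x, pseudocount = 1, n_lambda = 30,
                         lambda_min_ratio = 0.01, n_subsamples = 20,
                         subsample_size = NULL, beta_threshold = 0.05,
                         rule = c("or", "and"), seed = 1L) {
  rule <- match.arg(rule)
  clr <- clrTransform(x, pseudocount)
  path <- lambdaPath(clr, n_lambda, lambda_min_ratio)
  st <- starsSelect(clr, path, n_subsamples = n_subsamples,
                    subsample_size = subsample_size,
                    beta_threshold = beta_threshold, rule = rule, seed = seed)
  b <- neighborhoodLasso(clr, st$lambda_selected)
  rd <- as.data.frame(SummarizedExperiment::rowData(x))
  node_data <- data.frame(
    feature_id = rownames(x),
    domain_class = if ("domain_class" %in% names(rd)) rd$domain_class else NA_character_,
    mean_rel_abundance = rowMeans(relAbundance(x)),
    stringsAsFactors = FALSE)
  rownames(node_data) <- NULL
  st$params$pseudocount <- pseudocount
  st$params$lambda_path <- st$lambda_path
  buildNetwork(b, rule = rule, node_data = node_data,
               stability = st$edge_stability,
               lambda_selected = st$lambda_selected,
               instability = st$instability[st$index],
               params = st$params)
}

#' Convert an AssociationNetwork to igraph
#'
#' @param net an [AssociationNetwork-class].
#' @param weighted carry edge weights (default TRUE; topological metrics in
#'   this package use the unweighted graph).
#' @return an igraph graph with all node/edge attributes.
#' @export
asIgraph <- function(net, weighted = TRUE) {
  g <- igraph::graph_from_data_frame(net@edges, directed = FALSE,
                                     vertices = net@nodes)
  if (!weighted && igraph::ecount(g) > 0)
    g <- igraph::delete_edge_attr(g, "weight")
  g
}

#' Write network edge/node tables and GraphML
#'
#' @param net an [AssociationNetwork-class].
#' @param prefix file path prefix; writes `<prefix>_edges.tsv`,
#'   `<prefix>_nodes.tsv` and `<prefix>.graphml`.
#' @param graphml also write GraphML (default TRUE).
#' @return invisibly, the paths written.
#' @export
writeNetwork <- function(net, prefix, graphml = TRUE) {
  paths <- paste0(prefix, c("_edges.tsv", "_nodes.tsv"))
  utils::write.table(net@edges, paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(net@nodes, paths[2], sep = "\t", quote = FALSE, row.names = FALSE)
  if (graphml) {
    gpath <- paste0(prefix, ".graphml")
    igraph::write_graph(asIgraph(net), gpath, format = "graphml")
    paths <- c(paths, gpath)
  }
  invisible(paths)
}
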