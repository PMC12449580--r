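#' Shannon diversity index
#'
#' `H = -sum p_i log p_i` with natural logarithm, over the non-zero
#' proportions of a count (or abundance) vector. For a
#' `BiofilmExperiment` or matrix, one index per sample.
#'
#' @param x non-negative vector, features x samples matrix, or
#'   `BiofilmExperiment`.
#' @return numeric; named per-sample vector for matrix input.
#' @export
shannonIndex <- function(x) {
  if (methods::is(x, "BiofilmExperiment")) x <- counts(x)
  if (is.matrix(x)) {
    if (any(colSums(x) <= 0)) stop("shannonIndex: sample with zero total")
    return(vegan::diversity(t(x), index = "shannon"))
  }
  if (sum(x) <= 0) stop("shannonIndex: zero total")
  unname(vegan::diversity(x, index = "shannon"))
}

#' Bray-Curtis distance matrix
#'
#' `d(u, v) = 1 - 2 sum_j min(u_j, v_j) / (sum u + sum v)`, computed with
#' vegan. Operates on raw counts, copy-number-corrected abundances or
#' relative abundances; on relative abundances the result is invariant to
#' sequencing depth.
#'
#' @param x `BiofilmExperiment`, or features x samples matrix.
#' @param relative divide each sample by its total first (default TRUE).
#' @return symmetric square matrix (samples x samples) with zero diagonal,
#'   entries in \[0, 1\], sample IDs as dimnames.
#' @export
brayCurtis <- function(x, relative = TRUE) {
  m <- if (methods::is(x, "BiofilmExperiment")) counts(x) else as.matrix(x)
  if (ncol(m) < 2) stop("need at least 2 samples")
  if (any(colSums(m) <= 0)) stop("brayCurtis: sample with zero total")
  if (relative) m <- relAbundance(m)
  as.matrix(vegan::vegdist(t(m), method = "bray"))
}

.as_dist_matrix <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-8)
    stop("expected a symmetric square distance matrix")
  d
}

#' Principal coordinates analysis
#'
#' Gower double-centering of `-d^2 / 2` followed by eigen-decomposition.
#' Coordinates are eigenvectors scaled by the square root of their
#' (non-negative) eigenvalues; axes for negative eigenvalues — which arise
#' for semi-metric dissimilarities such as Bray-Curtis — are returned
#' separately so callers (notably [betaDispersion()]) can apply the
#' imaginary-part correction.
#'
#' @param d distance matrix (square symmetric, or `dist`).
#' @param n_axes number of positive-eigenvalue axes to retain (default all);
#'   requests beyond the positive-eigenvalue count are truncated with a
#'   warning.
#' @return list with `coordinates` (samples x axes), `eigenvalues`
#'   (descending, all of them), `proportion_explained` (per retained axis,
#'   relative to the positive eigenvalue total), and
#'   `negative_coordinates` (samples x axes for negative eigenvalues,
#'   scaled by `sqrt(-eigenvalue)`).
#' @export
pcoaOrdination <- function(d, n_axes = NULL) {
  d <- .as_dist_matrix(d)
  n <- nrow(d)
  a <- -0.5 * d^2
  centering <- diag(n) - matrix(1 / n, n, n)
  g <- centering %*% a %*% centering
  e <- eigen((g + t(g)) / 2, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9 + 1e-12
  pos <- which(e$values > tol)
  neg <- which(e$values < -tol)
  if (is.null(n_axes)) n_axes <- length(pos)
  if (n_axes > length(pos)) {
    warning("only ", length(pos), " positive-eigenvalue axes available")
    n_axes <- length(pos)
  }
  keep <- pos[seq_len(n_axes)]
  coords <- e$vectors[, keep, drop = FALSE] %*% diag(sqrt(e$values[keep]), length(keep))
  dimnames(coords) <- list(rownames(d), if (ncol(coords)) paste0("Axis", seq_len(ncol(coords))))
  negc <- e$vectors[, neg, drop = FALSE] %*% diag(sqrt(-e$values[neg]), length(neg))
  rownames(negc) <- rownames(d)
  list(coordinates = coords,
       eigenvalues = e$values,
       proportion_explained = e$values[keep] / sum(e$values[pos]),
       negative_coordinates = negc)
}

# Pseudo-F and R2 for one labelling of a squared-distance matrix.
.permanova_stat <- function(d2, groups) {
  n <- nrow(d2)
  lev <- unique(groups)
  ss_total <- sum(d2) / (2 * n)
  ss_within <- 0
  for (g in lev) {
    idx <- which(groups == g)
    ss_within <- ss_within + sum(d2[idx, idx]) / (2 * length(idx))
  }
  ss_between <- ss_total - ss_within
  a <- length(lev)
  f <- (ss_between / (a - 1)) / (ss_within / (n - a))
  c(F = f, R2 = ss_between / ss_total)
}

# All distinct assignments of a label multiset (columns = assignments).
.multiset_assignments <- function(labels) {
  lev <- unique(labels)
  n <- length(labels)
  rec <- function(free, remaining) {
    if (length(remaining) == 1) {
      out <- matrix(NA_character_, n, 1)
      out[free, 1] <- remaining[[1]]$label
      return(out)
    }
    k <- remaining[[1]]$count
    choices <- utils::combn(free, k)
    cols <- lapply(seq_len(ncol(choices)), function(j) {
      sub <- rec(setdiff(free, choices[, j]), remaining[-1])
      sub[choices[, j], ] <- remaining[[1]]$label
      sub
    })
    do.call(cbind, cols)
  }
  counts <- table(labels)
  remaining <- lapply(names(counts), function(l) list(label = l, count = unname(counts[l])))
  rec(seq_len(n), remaining)
}

.n_distinct_assignments <- function(labels) {
  tab <- table(labels)
  exp(lgamma(length(labels) + 1) - sum(lgamma(tab + 1)))
}

.permute_labels <- function(groups, strata) {
  if (is.null(strata)) return(sample(groups))
  out <- groups
  for (b in unique(strata)) {
    idx <- which(strata == b)
    out[idx] <- groups[idx][sample(length(idx))]
  }
  out
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' One-factor PERMANOVA on a distance matrix. The pseudo-F is
#' `(SS_between / (a - 1)) / (SS_within / (N - a))` with
#' `SS_total = sum_{i<j} d_ij^2 / N` and
#' `SS_within = sum_g sum_{i<j in g} d_ij^2 / n_g`;
#' `R2 = SS_between / SS_total`. Significance is assessed by shuffling the
#' group labels (within `strata` blocks when given). With sampled
#' permutations the p-value includes the observed statistic:
#' `p = (1 + #[F_perm >= F_obs]) / (n_perm + 1)`, so p is never 0. When the
#' number of distinct label assignments is no larger than `n_perm` (and no
#' strata are given) the complete distribution is enumerated instead and
#' `p = #[F >= F_obs] / n_assignments` over all assignments, the observed
#' one included.
#'
#' @param d distance matrix (square symmetric or `dist`).
#' @param groups factor-like vector of group labels, aligned with `d`.
#' @param n_perm number of permutations (default 999).
#' @param strata optional blocking vector; permutations stay within blocks.
#' @param seed RNG seed for reproducible permutations.
#' @param exact `"auto"` (enumerate when feasible), `"never"`, `"always"`.
#' @return one-row data.frame: `factor`, `df_between`, `df_within`, `F`,
#'   `R2`, `p`, `n_perm`, `method` (`"exact"` or `"sampled"`).
#' @export
permanovaTest <- function(d, groups, n_perm = 999, strata = NULL, seed = 1L,
                          exact = c("auto", "never", "always")) {
  exact <- match.arg(exact)
  d <- .as_dist_matrix(d)
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(d))
  lev <- unique(groups)
  if (length(lev) < 2) stop("factor must have at least 2 levels")
  if (any(table(groups) < 2)) stop("every group needs at least 2 samples")
  d2 <- d^2
  obs <- .permanova_stat(d2, groups)
  n_exact <- .n_distinct_assignments(groups)
  use_exact <- exact == "always" ||
    (exact == "auto" && is.null(strata) && n_exact <= n_perm)
  if (use_exact) {
    if (!is.null(strata)) stop("exact enumeration does not support strata")
    assigns <- .multiset_assignments(groups)
    fs <- apply(assigns, 2, function(gg) .permanova_stat(d2, gg)["F"])
    p <- mean(fs >= obs["F"] - 1e-12)
    method <- "exact"; n_used <- ncol(assigns)
  } else {
    set.seed(as.integer(seed))
    hits <- 0L
    for (i in seq_len(n_perm)) {
      fp <- .permanova_stat(d2, .permute_labels(groups, strata))["F"]
      if (fp >= obs["F"] - 1e-12) hits <- hits + 1L
    }
    p <- (1 + hits) / (n_perm + 1)
    method <- "sampled"; n_used <- n_perm
  }
  data.frame(factor = NA_character_, df_between = length(lev) - 1,
             df_within = nrow(d) - length(lev),
             F = unname(obs["F"]), R2 = unname(obs["R2"]), p = p,
             n_perm = n_used, method = method, stringsAsFactors = FALSE)
}

#' Distances to group centroids in PCoA space
#'
#' Per-sample distance to its group centroid computed over all PCoA axes,
#' with the imaginary-part convention for negative-eigenvalue axes:
#' `z_i^2 = d_pos^2 - d_neg^2`, truncated at zero.
#'
#' @param d distance matrix.
#' @param groups group labels.
#' @return named numeric vector of centroid distances.
#' @export
centroidDistances <- function(d, groups) {
  ord <- pcoaOrdination(d)
  pos <- ord$coordinates
  neg <- ord$negative_coordinates
  z <- numeric(nrow(pos))
  for (g in unique(groups)) {
    idx <- which(groups == g)
    cp <- colMeans(pos[idx, , drop = FALSE])
    cn <- if (ncol(neg)) colMeans(neg[idx, , drop = FALSE]) else numeric()
    dp2 <- rowSums(sweep(pos[idx, , drop = FALSE], 2, cp)^2)
    dn2 <- if (ncol(neg)) rowSums(sweep(neg[idx, , drop = FALSE], 2, cn)^2) else 0
    z[idx] <- sqrt(pmax(0, dp2 - dn2))
  }
  names(z) <- rownames(pos)
  z
}

.anova_f <- function(z, groups) {
  n <- length(z); lev <- unique(groups); a <- length(lev)
  gm <- mean(z)
  ssb <- sum(tapply(z, groups, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(tapply(z, groups, function(v) sum((v - mean(v))^2)))
  (ssb / (a - 1)) / (ssw / (n - a))
}

#' Homogeneity of multivariate dispersion
#'
#' Tests whether groups differ in spread: per-sample distances to the group
#' centroid (see [centroidDistances()]) are compared with a classical
#' one-way F statistic, whose significance is assessed by permuting group
#' labels over the fixed distances (exact enumeration as in
#' [permanovaTest()] when feasible).
#'
#' @inheritParams permanovaTest
#' @return one-row data.frame as in [permanovaTest()] (R2 is the
#'   between-group fraction of the dispersion sum of squares).
#' @export
betaDispersion <- function(d, groups, n_perm = 999, seed = 1L,
                           exact = c("auto", "never", "always")) {
  exact <- match.arg(exact)
  d <- .as_dist_matrix(d)
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(d))
  lev <- unique(groups)
  if (length(lev) < 2) stop("factor must have at least 2 levels")
  if (any(table(groups) < 2)) stop("every group needs at least 2 samples")
  z <- centroidDistances(d, groups)
  f_obs <- .anova_f(z, groups)
  n_exact <- .n_distinct_assignments(groups)
  use_exact <- exact == "always" || (exact == "auto" && n_exact <= n_perm)
  if (use_exact) {
    assigns <- .multiset_assignments(groups)
    fs <- apply(assigns, 2, function(gg) .anova_f(z, gg))
    p <- mean(fs >= f_obs - 1e-12)
    method <- "exact"; n_used <- ncol(assigns)
  } else {
    set.seed(as.integer(seed))
    hits <- sum(replicate(n_perm, .anova_f(z, sample(groups))) >= f_obs - 1e-12)
    p <- (1 + hits) / (n_perm + 1)
    method <- "sampled"; n_used <- n_perm
  }
  gm <- mean(z)
  ssb <- sum(tapply(z, groups, function(v) length(v) * (mean(v) - gm)^2))
  sst <- sum((z - gm)^2)
  data.frame(factor = NA_character_, df_between = length(lev) - 1,
             df_within = length(z) - length(lev),
             F = f_obs, R2 = ssb / sst, p = p, n_perm = n_used,
             method = method, stringsAsFactors = FALSE)
}

#' Pairwise PERMANOVA with multiplicity correction
#'
#' One PERMANOVA per pair of groups on the corresponding sub-matrix of `d`,
#' with p-values adjusted by Benjamini-Hochberg (default) or Bonferroni.
#'
#' @inheritParams permanovaTest
#' @param correction `"BH"` or `"bonferroni"`.
#' @return data.frame with one row per pair: `group1`, `group2`, plus the
#'   [permanovaTest()] columns and `p_adj`.
#' @export
pairwisePermanova <- function(d, groups, n_perm = 999, seed = 1L,
                              correction = c("BH", "bonferroni"),
                              exact = c("auto", "never", "always")) {
  correction <- match.arg(correction)
  exact <- match.arg(exact)
  d <- .as_dist_matrix(d)
  groups <- as.character(groups)
  lev <- unique(groups)
  if (length(lev) < 2) stop("need at least 2 groups")
  pairs <- utils::combn(lev, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    keep <- groups %in% pairs[, j]
    res <- permanovaTest(d[keep, keep], groups[keep], n_perm = n_perm,
                         seed = seed + j, exact = exact)
    cbind(group1 = pairs[1, j], group2 = pairs[2, j], res)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = correction)
  out
}
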