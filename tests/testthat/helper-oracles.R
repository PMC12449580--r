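# Independent oracles used to freeze or cross-check expected values.
# These deliberately re-derive each quantity from first principles through a
# different code path than the package.

# Coordinate-descent lasso for standardized columns, no intercept:
# minimizes ||y - X b||^2 / (2 n) + lambda * ||b||_1.
oracle_lasso <- function(x, y, lambda, n_iter = 2000, tol = 1e-12) {
  n <- nrow(x); p <- ncol(x)
  b <- rep(0, p)
  xtx_n <- colSums(x^2) / n
  soft <- function(z, g) sign(z) * pmax(abs(z) - g, 0)
  for (it in seq_len(n_iter)) {
    b_old <- b
    for (j in seq_len(p)) {
      r <- y - x[, -j, drop = FALSE] %*% b[-j]
      b[j] <- soft(sum(x[, j] * r) / n, lambda) / xtx_n[j]
    }
    if (max(abs(b - b_old)) < tol) break
  }
  b
}

# All set partitions of 1..n via restricted growth strings.
oracle_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, m) {
    k <- length(prefix)
    if (k == n) { out[[length(out) + 1]] <<- prefix; return() }
    for (v in seq_len(m + 1)) rec(c(prefix, v), max(m, v))
  }
  rec(integer(), 0L)
  out
}

# Newman-Girvan modularity of a partition, written out longhand.
oracle_modularity <- function(adj, memb) {
  e_total <- sum(adj) / 2
  if (e_total == 0) return(0)
  q <- 0
  for (m in unique(memb)) {
    idx <- which(memb == m)
    within <- sum(adj[idx, idx]) / 2
    deg_sum <- sum(adj[idx, ])
    q <- q + within / e_total - (deg_sum / (2 * e_total))^2
  }
  q
}

# Best modularity over all partitions (feasible for <= 8 nodes).
oracle_best_modularity <- function(adj) {
  parts <- oracle_partitions(nrow(adj))
  max(vapply(parts, function(p) oracle_modularity(adj, p), numeric(1)))
}

# PERMANOVA pseudo-F via explicit double loops over sample pairs.
oracle_pseudo_f <- function(d, groups) {
  n <- nrow(d)
  ss_tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) ss_tot <- ss_tot + d[i, j]^2
  ss_tot <- ss_tot / n
  ss_w <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    acc <- 0
    if (length(idx) > 1)
      for (a in seq_len(length(idx) - 1)) for (b in (a + 1):length(idx))
        acc <- acc + d[idx[a], idx[b]]^2
    ss_w <- ss_w + acc / length(idx)
  }
  a <- length(unique(groups))
  ((ss_tot - ss_w) / (a - 1)) / (ss_w / (n - a))
}

# Exact 3-vs-3 enumeration of pseudo-F p-value: all choose(6,3) = 20
# assignments of group A positions.
oracle_exact_p_3v3 <- function(stat_fn, d_or_z) {
  combos <- utils::combn(6, 3)
  obs <- stat_fn(d_or_z, c("A", "A", "A", "B", "B", "B"))
  fs <- apply(combos, 2, function(ix) {
    gg <- rep("B", 6); gg[ix] <- "A"
    stat_fn(d_or_z, gg)
  })
  mean(fs >= obs - 1e-12)
}

# One-way ANOVA F through stats::anova, for beta-dispersion cross-checks.
oracle_anova_f <- function(z, groups)
  stats::anova(stats::lm(z ~ factor(groups)))$`F value`[1]
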