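test_that("Shannon index matches closed forms and direct summation", {
  expect_equal(shannonIndex(c(5, 5, 5, 5)), log(4))
  expect_equal(shannonIndex(c(7, 0, 0)), 0)
  expect_equal(shannonIndex(c(1, 2, 3, 4)), 1.279854, tolerance = 1e-6)
  p <- c(1, 2, 3, 4) / 10
  expect_equal(shannonIndex(c(1, 2, 3, 4)), -sum(p * log(p)))
  expect_error(shannonIndex(c(0, 0)), "zero total")
})

test_that("Bray-Curtis matches the formula and vegan, and is depth-invariant on proportions", {
  m <- cbind(u = c(6, 4, 0), v = c(2, 4, 4))
  rownames(m) <- paste0("f", 1:3)
  d <- brayCurtis(m, relative = FALSE)
  expect_equal(d["u", "v"], 0.4)
  expect_equal(d["u", "u"], 0)
  disj <- cbind(a = c(1, 0), b = c(0, 1))
  expect_equal(brayCurtis(disj, relative = FALSE)["a", "b"], 1)
  set.seed(41)
  mm <- matrix(rpois(60, 20) + 1, 6, 10,
               dimnames = list(paste0("f", 1:6), paste0("s", 1:10)))
  expect_equal(brayCurtis(mm, relative = FALSE),
               as.matrix(vegan::vegdist(t(mm), "bray")))
  # raw Bray-Curtis depends on depth; on relative abundances it does not
  scaled <- sweep(mm, 2, sample(1:5, 10, TRUE), "*")
  expect_false(isTRUE(all.equal(brayCurtis(mm, relative = FALSE),
                                brayCurtis(scaled, relative = FALSE))))
  expect_equal(brayCurtis(mm), brayCurtis(scaled))
})

test_that("PCoA reconstructs Euclidean configurations and flags identical samples", {
  x <- c(0, 3, 10)
  d <- as.matrix(dist(x)); dimnames(d) <- list(letters[1:3], letters[1:3])
  ord <- pcoaOrdination(d)
  expect_equal(as.matrix(dist(ord$coordinates[, 1])), d, ignore_attr = TRUE)
  # full-rank reconstruction for a Euclidean-embeddable input
  set.seed(42)
  pts <- matrix(rnorm(5 * 3), 5)
  d2 <- as.matrix(dist(pts)); dimnames(d2) <- list(paste0("s", 1:5), paste0("s", 1:5))
  ord2 <- pcoaOrdination(d2)
  expect_equal(as.matrix(dist(ord2$coordinates)), d2, ignore_attr = TRUE)
  expect_true(all(diff(ord2$eigenvalues) <= 1e-9))
  expect_lte(sum(ord2$proportion_explained), 1 + 1e-9)
  # identical samples collapse to the origin
  d0 <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_equal(ncol(pcoaOrdination(d0)$coordinates), 0)
  expect_warning(pcoaOrdination(d2, n_axes = 10), "positive-eigenvalue")
  # agrees with cmdscale up to sign
  cm <- cmdscale(d2, k = 2)
  expect_equal(abs(ord2$coordinates[, 1:2]), abs(cm), ignore_attr = TRUE)
})

test_that("PERMANOVA agrees with vegan's pseudo-F and R2", {
  set.seed(43)
  m <- matrix(rpois(80, 20) + 1, 8, 10,
              dimnames = list(paste0("f", 1:8), paste0("s", 1:10)))
  gr <- rep(c("A", "B"), each = 5)
  d <- brayCurtis(m, relative = FALSE)
  mine <- permanovaTest(d, gr, n_perm = 99, seed = 1)
  ref <- vegan::adonis2(as.dist(d) ~ gr, permutations = 99)
  expect_equal(mine$F, ref$F[1], tolerance = 1e-10)
  expect_equal(mine$R2, ref$R2[1], tolerance = 1e-10)
  expect_equal(mine$df_between, ref$Df[1])
  # R2 = SS_between / SS_total, so R2 + SS_within/SS_total = 1 exactly
  n <- nrow(d)
  ss_tot <- sum(d^2) / (2 * n)
  ss_w <- sum(vapply(unique(gr), function(g) {
    idx <- gr == g
    sum(d[idx, idx]^2) / (2 * sum(idx))
  }, numeric(1)))
  expect_equal(mine$R2 + ss_w / ss_tot, 1, tolerance = 1e-12)
  expect_equal(mine$F, oracle_pseudo_f(d, gr), tolerance = 1e-10)
})

test_that("exact enumeration reproduces the full 3-vs-3 permutation distribution", {
  set.seed(44)
  m <- matrix(rpois(36, 15) + 1, 6, 6,
              dimnames = list(paste0("f", 1:6), paste0("s", 1:6)))
  gr <- rep(c("A", "B"), each = 3)
  d <- brayCurtis(m, relative = FALSE)
  res <- permanovaTest(d, gr, n_perm = 999)
  expect_identical(res$method, "exact")
  expect_identical(res$n_perm, 20L)
  expect_equal(res$p, oracle_exact_p_3v3(oracle_pseudo_f, d))
  bd <- betaDispersion(d, gr, n_perm = 999)
  expect_identical(bd$method, "exact")
  z <- centroidDistances(d, gr)
  # under relabelling, centroid distances are recomputed on fixed z
  expect_equal(bd$p, oracle_exact_p_3v3(function(zz, gg) phyconet:::.anova_f(zz, gg), z))
})

test_that("sampled permutation p-values are reproducible and bounded below", {
  set.seed(45)
  m <- matrix(rpois(120, 20) + 1, 6, 20,
              dimnames = list(paste0("f", 1:6), paste0("s", 1:20)))
  gr <- rep(c("A", "B"), each = 10)
  d <- brayCurtis(m, relative = FALSE)
  r1 <- permanovaTest(d, gr, n_perm = 199, seed = 7, exact = "never")
  r2 <- permanovaTest(d, gr, n_perm = 199, seed = 7, exact = "never")
  expect_identical(r1$p, r2$p)
  expect_gte(r1$p, 1 / 200)
  r3 <- permanovaTest(d, gr, n_perm = 199, seed = 8, exact = "never")
  expect_true(abs(r3$p - r1$p) < 0.2)  # same distribution, different draw
})

test_that("identical composition in both groups gives a large PERMANOVA p", {
  base <- matrix(rpois(30, 20) + 1, 6, 5)
  m <- cbind(base, base)   # group B duplicates group A exactly
  rownames(m) <- paste0("f", 1:6); colnames(m) <- paste0("s", 1:10)
  gr <- rep(c("A", "B"), each = 5)
  d <- brayCurtis(m, relative = FALSE)
  res <- permanovaTest(d, gr, n_perm = 199, seed = 1, exact = "never")
  expect_true(is.finite(res$F))
  expect_gte(res$p, 0.5)
})

test_that("beta dispersion matches vegan's centroid distances and detects spread differences", {
  set.seed(46)
  m <- matrix(rpois(140, 25) + 1, 7, 20,
              dimnames = list(paste0("f", 1:7), paste0("s", 1:20)))
  gr <- rep(c("A", "B"), each = 10)
  d <- brayCurtis(m, relative = FALSE)
  z <- centroidDistances(d, gr)
  ref <- vegan::betadisper(as.dist(d), gr, type = "centroid")
  expect_equal(unname(z), unname(ref$distances), tolerance = 1e-8)
  expect_equal(phyconet:::.anova_f(z, gr), oracle_anova_f(z, gr), tolerance = 1e-10)
  # zero-spread group vs spread group -> small p
  tight <- matrix(rep(c(5, 10, 20), 6), 3)
  loose <- matrix(rpois(18, 10) + 1, 3)
  m2 <- cbind(tight, loose)
  rownames(m2) <- paste0("f", 1:3); colnames(m2) <- paste0("s", 1:12)
  d2 <- brayCurtis(m2, relative = FALSE)
  g2 <- rep(c("T", "L"), each = 6)
  expect_lte(betaDispersion(d2, g2, n_perm = 999, seed = 1)$p, 0.05)
  # mirror-image point sets have equal spread -> large p
  pts <- matrix(rnorm(12), 6, 2)
  pts2 <- rbind(pts, -pts)
  dm <- as.matrix(dist(pts2))
  dimnames(dm) <- list(paste0("s", 1:12), paste0("s", 1:12))
  gm <- rep(c("A", "B"), each = 6)
  expect_gte(betaDispersion(dm, gm, n_perm = 199, seed = 1, exact = "never")$p, 0.3)
})

test_that("pairwise PERMANOVA adjusts p-values as Benjamini-Hochberg prescribes", {
  set.seed(47)
  m <- matrix(rpois(180, 20) + 1, 6, 30,
              dimnames = list(paste0("f", 1:6), paste0("s", 1:30)))
  gr <- rep(c("A", "B", "C"), each = 10)
  d <- brayCurtis(m, relative = FALSE)
  pw <- pairwisePermanova(d, gr, n_perm = 99, seed = 1)
  expect_equal(nrow(pw), 3)
  expect_equal(pw$p_adj, p.adjust(pw$p, "BH"))
  expect_equal(p.adjust(c(0.01, 0.02, 0.04), "BH"), c(0.03, 0.03, 0.04))
  # two groups only: adjusted equals raw
  pw2 <- pairwisePermanova(d[1:20, 1:20], gr[1:20], n_perm = 99, seed = 1)
  expect_equal(pw2$p_adj, pw2$p)
  pwb <- pairwisePermanova(d, gr, n_perm = 99, seed = 1, correction = "bonferroni")
  expect_equal(pwb$p_adj, pmin(1, pwb$p * 3))
})

test_that("strata restrict permutations to within blocks", {
  set.seed(48)
  m <- matrix(rpois(96, 18) + 1, 8, 12,
              dimnames = list(paste0("f", 1:8), paste0("s", 1:12)))
  gr <- rep(c("A", "B"), 6)
  strata <- rep(paste0("blk", 1:6), each = 2)
  d <- brayCurtis(m, relative = FALSE)
  res <- permanovaTest(d, gr, n_perm = 99, strata = strata, seed = 3)
  expect_identical(res$method, "sampled")
  expect_true(res$p >= 1 / 100 && res$p <= 1)
})
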