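test_that("WMC filter applies both exclusion rules exactly", {
  # feature 1: 2 total reads -> removed; feature 2: abundant -> kept
  m <- rbind(f01 = c(1, 1, 0, 0),
             f02 = c(30, 25, 20, 25),
             f03 = c(5000, 6000, 5500, 5800),
             f04 = c(3000, 3200, 2900, 3100))
  colnames(m) <- paste0("s", 1:4)
  be <- toy_be(m)
  kept <- rownames(wmcFilter(be))
  expect_false("f01" %in% kept)
  expect_true("f02" %in% kept)  # ~0.3% mean abundance, 100 reads
  # exhaustive enumeration on a random 30-feature table
  set.seed(51)
  mm <- matrix(rnbinom(30 * 8, mu = 40, size = 0.3), 30, 8)
  mm[1, ] <- 900
  rownames(mm) <- sprintf("f%02d", 1:30); colnames(mm) <- paste0("s", 1:8)
  ra <- sweep(mm, 2, colSums(mm), "/")
  expected <- rownames(mm)[rowSums(mm) >= 3 & rowMeans(ra) >= 0.0025]
  got <- rownames(wmcFilter(toy_be(mm)))
  expect_setequal(got, expected)
  expect_error(wmcFilter(toy_be(mm), min_total_reads = 1e6), "fewer than 3")
})

test_that("CLR transform matches its closed forms and always centers rows", {
  m1 <- matrix(1, 4, 1, dimnames = list(paste0("f", 1:4), "s1"))
  expect_equal(unname(clrTransform(m1, pseudocount = 0)[1, ]), rep(0, 4))
  m2 <- matrix(c(2, 8), 2, 1, dimnames = list(c("a", "b"), "s1"))
  expect_equal(unname(clrTransform(m2, pseudocount = 0)[1, ]),
               c(-0.693147, 0.693147), tolerance = 1e-6)
  set.seed(52)
  mm <- matrix(rpois(50, 10), 10, 5,
               dimnames = list(paste0("f", 1:10), paste0("s", 1:5)))
  cl <- clrTransform(mm, pseudocount = 1)
  expect_true(all(abs(rowSums(cl)) < 1e-9))
  mm[1, 1] <- 0L
  expect_error(clrTransform(mm, pseudocount = 0), "pseudocount")
})

test_that("no neighborhood survives at or above lambda_max", {
  set.seed(53)
  mm <- matrix(rpois(200, 30), 20, 10,
               dimnames = list(paste0("f", 1:20), paste0("s", 1:10)))
  cl <- clrTransform(mm)
  lmax <- lambdaMax(cl)
  b <- neighborhoodLasso(cl, lmax * 1.0001)
  expect_true(all(b == 0))
  b2 <- neighborhoodLasso(cl, lmax * 0.3)
  expect_gt(sum(b2 != 0), 0)
})

test_that("duplicated features find each other as mutual neighbors", {
  set.seed(54)
  x <- matrix(rnorm(20 * 5), 20, 5)
  x[, 2] <- x[, 1] + rnorm(20, sd = 0.01)
  colnames(x) <- paste0("f", 1:5)
  b <- neighborhoodLasso(x, 0.1)
  expect_true(b[1, 2] != 0 && b[2, 1] != 0)
  expect_true(all(abs(b[1, -c(1, 2)]) < 0.05))
})

test_that("glmnet coefficients agree with a coordinate-descent oracle", {
  set.seed(55)
  x <- matrix(rnorm(25 * 6), 25, 6)
  x[, 3] <- 0.7 * x[, 1] + rnorm(25, sd = 0.5)
  colnames(x) <- paste0("f", 1:6)
  xs <- phyconet:::.standardize_cols(x)
  for (lambda in c(0.05, 0.15, 0.3)) {
    b <- neighborhoodLasso(x, lambda)
    for (j in c(1, 3)) {
      ref <- oracle_lasso(xs[, -j, drop = FALSE], xs[, j], lambda)
      expect_equal(unname(b[j, -j]), ref, tolerance = 1e-6,
                   label = paste("lambda", lambda, "node", j))
    }
  }
})

test_that("StARS selects the densest penalty when subsample graphs never vary", {
  set.seed(56)
  mm <- matrix(rpois(30 * 12, 40), 30, 12,
               dimnames = list(paste0("f", 1:30), paste0("s", 1:12)))
  cl <- clrTransform(mm)
  path <- lambdaPath(cl, n_lambda = 8)
  # subsample size equal to n: every subsample is the full data set
  st <- starsSelect(cl, path, n_subsamples = 5, subsample_size = nrow(cl),
                    beta_threshold = 0.05, seed = 1)
  expect_equal(st$instability_raw, rep(0, 8))
  expect_equal(st$index, 8L)
  expect_equal(st$lambda_selected, min(path))
  # instability is mean 2*theta*(1-theta) over pairs, recomputed from the
  # returned stability matrix at the selected penalty
  inst <- 2 * st$edge_stability * (1 - st$edge_stability)
  expect_equal(mean(inst[upper.tri(inst)]), st$instability_raw[st$index])
})

test_that("StARS falls back to the sparsest penalty when nothing is stable", {
  set.seed(57)
  mm <- matrix(rpois(10 * 20, 30), 10, 20,
               dimnames = list(paste0("f", 1:10), paste0("s", 1:20)))
  cl <- clrTransform(mm)
  path <- lambdaPath(cl, n_lambda = 5, min_ratio = 1e-4)
  expect_warning(
    st <- starsSelect(cl, path, n_subsamples = 8, subsample_size = 8,
                      beta_threshold = 1e-6, seed = 2),
    "sparsest")
  expect_equal(st$index, 1L)
})

test_that("symmetrization follows the or/and rule and the sign-conflict policy", {
  ids <- c("a", "b", "c")
  b <- matrix(0, 3, 3, dimnames = list(ids, ids))
  b["a", "b"] <- 0.4; b["b", "a"] <- 0.2      # agreeing pair
  b["a", "c"] <- 0.3; b["c", "a"] <- -0.1     # conflicting pair
  b["b", "c"] <- 0.5                          # one-sided
  net <- buildNetwork(b, rule = "or")
  e <- networkEdges(net)
  expect_equal(e$weight[e$from == "a" & e$to == "b"], 0.3)
  expect_equal(e$sign[e$from == "a" & e$to == "b"], "+")
  expect_equal(e$weight[e$from == "a" & e$to == "c"], 0.3)  # larger magnitude wins
  expect_equal(net@params$sign_conflicts, 1L)
  expect_equal(e$weight[e$from == "b" & e$to == "c"], 0.25) # mean with the 0
  net_and <- buildNetwork(b, rule = "and")
  ea <- networkEdges(net_and)
  expect_equal(nrow(ea), 2)                   # one-sided pair drops under "and"
  expect_false(any(ea$from == "b" & ea$to == "c"))
  # empty coefficient pair -> no edge
  b0 <- matrix(0, 3, 3, dimnames = list(ids, ids))
  expect_equal(nrow(networkEdges(buildNetwork(b0))), 0)
})

test_that("inference is seed-reproducible and invariant to feature order", {
  g <- makeGraph(20, "band", density = 0.1, seed = 61)
  d <- singleGroupDesign(n = 40, depth_mean = 5000, seed = 61)
  x <- simulateCounts(g, d)
  n1 <- inferNetwork(x, n_lambda = 10, n_subsamples = 8, seed = 9)
  n2 <- inferNetwork(x, n_lambda = 10, n_subsamples = 8, seed = 9)
  expect_identical(networkEdges(n1), networkEdges(n2))
  expect_identical(n1@lambdaSelected, n2@lambdaSelected)
  # permute features: same edges up to ID mapping
  x_perm <- x[sample(nrow(x)), ]
  n3 <- inferNetwork(x_perm, n_lambda = 10, n_subsamples = 8, seed = 9)
  key <- function(net) {
    e <- networkEdges(net)
    sort(paste(pmin(e$from, e$to), pmax(e$from, e$to)))
  }
  expect_identical(key(n3), key(n1))
})

test_that("inferred networks beat size-matched random graphs on synthetic truth", {
  set.seed(62)
  g <- makeGraph(30, "band", density = 29 / choose(30, 2), seed = 62)
  d <- singleGroupDesign(n = 80, depth_mean = 10000, seed = 62)
  x <- simulateCounts(g, d)
  net <- inferNetwork(x, n_lambda = 15, n_subsamples = 10, seed = 3)
  truth <- truthEdgeSet(g)
  f1 <- edgeRecovery(net, truth)["f1"]
  ids <- rownames(x)
  n_edges <- nrow(networkEdges(net))
  rand_f1 <- replicate(50, {
    pairs <- t(combn(ids, 2))[sample(choose(30, 2), n_edges), , drop = FALSE]
    fake <- list(edges = data.frame(from = pairs[, 1], to = pairs[, 2]))
    class(fake) <- "list"
    est <- paste(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
    tru <- paste(truth$from, truth$to)
    tp <- length(intersect(est, tru))
    prec <- tp / n_edges; rec <- tp / nrow(truth)
    if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  })
  expect_gt(unname(f1), max(rand_f1))
})
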