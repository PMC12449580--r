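test_that("basic metrics match hand counts on canonical graphs", {
  tri <- toy_network(rbind(c(1, 2), c(2, 3), c(1, 3)))
  bm <- basicMetrics(tri)
  expect_equal(unname(bm[c("mean_degree", "edge_density", "transitivity")]),
               c(2, 1, 1))
  empty <- toy_network(rbind(c(1, 2)), n_nodes = 5)
  empty@edges <- empty@edges[0, ]
  bm0 <- basicMetrics(empty)
  expect_equal(unname(bm0[c("edge_density", "mean_degree", "prop_negative_edges",
                            "mean_abs_weight", "transitivity")]),
               c(0, 0, 0, 0, 0))
  # K4 minus one edge: 2 triangles, 8 connected triples -> 3*2/8
  k4m <- toy_network(rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4)))
  expect_equal(unname(basicMetrics(k4m)["transitivity"]), 0.75)
  neg <- toy_network(rbind(c(1, 2), c(2, 3)), weights = c(1, -2))
  bmn <- basicMetrics(neg)
  expect_equal(unname(bmn["prop_negative_edges"]), 0.5)
  expect_equal(unname(bmn["mean_abs_weight"]), 1.5)
})

test_that("natural connectivity matches closed forms and increases with every edge", {
  empty <- toy_network(rbind(c(1, 2)), n_nodes = 5)
  empty@edges <- empty@edges[0, ]
  expect_equal(naturalConnectivity(empty), 0)
  tri <- toy_network(rbind(c(1, 2), c(2, 3), c(1, 3)))
  expect_equal(naturalConnectivity(tri), log((exp(2) + 2 * exp(-1)) / 3),
               tolerance = 1e-12)
  expect_equal(naturalConnectivity(tri), 0.99635, tolerance = 1e-4)
  set.seed(71)
  for (r in 1:100) {
    n <- sample(5:10, 1)
    a <- matrix(0, n, n)
    pairs <- t(combn(n, 2))
    on <- sample(nrow(pairs), sample(2:(nrow(pairs) - 1), 1))
    a[pairs[on, , drop = FALSE]] <- 1
    a <- a + t(a)
    off <- setdiff(seq_len(nrow(pairs)), on)
    add <- pairs[off[sample.int(length(off), 1)], ]
    a2 <- a; a2[add[1], add[2]] <- a2[add[2], add[1]] <- 1
    expect_gt(naturalConnectivity(a2), naturalConnectivity(a))
  }
})

test_that("module detection attains the exhaustive-partition modularity optimum", {
  graphs <- list(
    two_triangles = rbind(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6)),
    path6 = cbind(1:5, 2:6),
    k4_minus = rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4)),
    barbell = rbind(c(1, 2), c(2, 3), c(1, 3), c(3, 4), c(4, 5), c(5, 6), c(4, 6)),
    star7 = cbind(rep(1, 6), 2:7))
  set.seed(72)
  graphs$random8 <- t(combn(8, 2))[runif(28) < 0.35, ]
  for (nm in names(graphs)) {
    net <- toy_network(graphs[[nm]])
    part <- detectModules(net, n_restarts = 10, seed = 5)
    adj <- as.matrix(igraph::as_adjacency_matrix(asIgraph(net, FALSE), sparse = FALSE))
    best <- oracle_best_modularity(adj)
    expect_equal(part@Q, best, tolerance = 1e-9, label = nm)
    # and the reported Q is the Q of the reported membership
    memb <- moduleMembership(part)[rownames(adj)]
    expect_equal(oracle_modularity(adj, memb), part@Q, tolerance = 1e-12)
  }
})

test_that("two disjoint triangles split into components with Q = 0.5", {
  net <- toy_network(rbind(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6)))
  part <- detectModules(net, seed = 1)
  expect_equal(part@Q, 0.5)
  memb <- moduleMembership(part)
  expect_equal(length(unique(memb[1:3])), 1)
  expect_equal(length(unique(memb[4:6])), 1)
  expect_false(memb[["n01"]] == memb[["n04"]])
  # whole graph as one module has Q = 0
  adj <- as.matrix(igraph::as_adjacency_matrix(asIgraph(net, FALSE), sparse = FALSE))
  expect_equal(oracle_modularity(adj, rep(1, 6)), 0)
  # edgeless graph: single module, Q = 0 by convention
  e0 <- net; e0@edges <- e0@edges[0, ]
  p0 <- detectModules(e0, seed = 1)
  expect_equal(p0@Q, 0)
  expect_equal(unname(unique(moduleMembership(p0))), 1L)
})

test_that("Zi and Pi match the hand-computed table on the 10-node toy graph", {
  tz <- zipi_toy()
  roles <- ziPi(tz$net, tz$part)
  roles <- roles[order(roles$node), ]
  expect_equal(roles$Zi,
               c(1.6329931619, 0, 0, -0.8164965809, -0.8164965809,
                 1.788854382, -0.4472135955, -0.4472135955, -0.4472135955,
                 -0.4472135955),
               tolerance = 1e-9)
  expect_equal(roles$Pi,
               c(0, 0, 0.4444444444, 0, 0.5, 0.32, 0.4444444444, 0, 0, 0),
               tolerance = 1e-9)
  expect_equal(roles$degree, c(4, 2, 3, 1, 2, 5, 3, 2, 2, 2))
  # node with all edges inside its module has Pi = 0
  expect_equal(roles$Pi[roles$node == "n01"], 0)
  # degree conservation across modules
  adj <- as.matrix(igraph::as_adjacency_matrix(asIgraph(tz$net, FALSE), sparse = FALSE))
  memb <- moduleMembership(tz$part)[rownames(adj)]
  for (i in seq_len(nrow(adj))) {
    k_im <- vapply(unique(memb), function(m) sum(adj[i, memb == m]), numeric(1))
    expect_equal(sum(k_im), sum(adj[i, ]))
  }
})

test_that("role classes follow the Zi/Pi thresholds and survive module relabeling", {
  tz <- zipi_toy()
  roles <- ziPi(tz$net, tz$part, z_thresh = 1.5, p_thresh = 0.4)
  expect_equal(roles$role[roles$node == "n01"], "module_hub")   # Zi 1.63, Pi 0
  expect_equal(roles$role[roles$node == "n05"], "connector")    # Zi -0.82, Pi 0.5
  expect_equal(roles$role[roles$node == "n02"], "peripheral")
  # node with 4 edges split evenly across 2 modules: Pi = 0.5
  evenly <- toy_network(rbind(c(1, 2), c(1, 3), c(1, 4), c(1, 5), c(2, 3), c(4, 5)))
  p2 <- methods::new("ModulePartition",
    membership = setNames(c(1L, 2L, 2L, 3L, 3L), sprintf("n%02d", 1:5)),
    Q = 0, method = "fixed", seed = 0L)
  r2 <- ziPi(evenly, p2)
  expect_equal(r2$Pi[r2$node == "n01"], 0.5)
  # relabeled modules give identical roles
  relab <- tz$part
  relab@membership <- setNames(3L - relab@membership, names(relab@membership))
  roles_rl <- ziPi(tz$net, relab, z_thresh = 1.5, p_thresh = 0.4)
  expect_equal(roles_rl$role, roles$role)
  expect_equal(roles_rl$Zi, roles$Zi)
  # isolated node: Zi = 0, Pi = 0, peripheral
  iso <- toy_network(rbind(c(1, 2)), n_nodes = 3)
  ri <- ziPi(iso, detectModules(iso, seed = 1))
  expect_equal(ri[ri$node == "n03", c("Zi", "Pi")], data.frame(Zi = 0, Pi = 0),
               ignore_attr = TRUE)
  expect_equal(ri$role[ri$node == "n03"], "peripheral")
})

test_that("the network profile assembles all metrics in fixed order", {
  tri <- toy_network(rbind(c(1, 2), c(2, 3), c(1, 3)))
  pr <- networkProfile(tri, seed = 1)
  expect_identical(names(pr),
    c("n_nodes", "n_edges", "edge_density", "mean_degree", "mean_betweenness",
      "transitivity", "modularity_Q", "natural_connectivity",
      "prop_negative_edges", "mean_abs_weight"))
  expect_equal(unname(pr), c(3, 3, 1, 2, 0, 1, 0, 0.99635, 0, 1), tolerance = 1e-4)
  # permuted node order leaves the profile unchanged
  tri_perm <- toy_network(rbind(c(3, 1), c(1, 2), c(3, 2)))
  expect_equal(networkProfile(tri_perm, seed = 1), pr)
  # empty graph: edge-dependent fields are 0
  e0 <- tri; e0@edges <- e0@edges[0, ]
  pr0 <- networkProfile(e0, seed = 1)
  expect_equal(unname(pr0[c("n_edges", "edge_density", "mean_degree",
                            "transitivity", "modularity_Q",
                            "natural_connectivity", "mean_abs_weight")]),
               rep(0, 7))
})
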