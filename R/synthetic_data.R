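#' Simulation design for grouped compositional count data
#'
#' Describes the experimental layout and generative parameters used by
#' [simulateCounts()]: the sample groups (host treatment x substrate x
#' timepoint with replicate counts), sequencing-depth distribution, planted
#' core and host-specific feature sets, the treatment effect size, and how
#' structural prevalence is enforced.
#'
#' @slot groups data.frame(treatment, substrate, timepoint, n_replicates).
#' @slot depthMean,depthDispersion log-normal sequencing-depth parameters
#'   (mean on the natural scale; dispersion = sdlog).
#' @slot coreSpec named list: group label (`treatment|substrate`) -> feature
#'   ids planted as that group's core (boosted, high structural prevalence).
#' @slot hostSpecificSpec named list: host treatment -> feature ids present
#'   only in that host's biofilm and proxy-biofilm groups.
#' @slot effectSize log-scale mean shift distinguishing treatments (0 = null).
#' @slot corePrevalence,backgroundPrevalence target structural prevalence of
#'   planted core features and of all other features within a group.
#' @slot coreBoost log-scale mean boost of planted core / host-specific
#'   features inside their groups.
#' @slot dropoutMode `"fixed"` (zero exactly `floor((1-prev) * n)` samples per
#'   group, guaranteeing the realised structural prevalence never falls below
#'   target), `"bernoulli"` (independent per-sample dropout), or `"none"`.
#' @slot seed integer RNG seed; a fixed seed makes [simulateCounts()]
#'   bit-reproducible.
#' @export
setClass("SimulationDesign",
  representation(groups = "data.frame", depthMean = "numeric",
                 depthDispersion = "numeric", coreSpec = "list",
                 hostSpecificSpec = "list", effectSize = "numeric",
                 corePrevalence = "numeric", backgroundPrevalence = "numeric",
                 coreBoost = "numeric", dropoutMode = "character",
                 seed = "integer"))

setValidity("SimulationDesign", function(object) {
  msg <- character()
  g <- object@groups
  if (!all(c("treatment", "substrate", "timepoint", "n_replicates") %in% names(g)))
    msg <- c(msg, "groups needs treatment, substrate, timepoint, n_replicates")
  else if (any(g$n_replicates < 1)) msg <- c(msg, "replicate counts must be >= 1")
  if (object@effectSize < 0) msg <- c(msg, "effectSize must be >= 0")
  if (!object@dropoutMode %in% c("fixed", "bernoulli", "none"))
    msg <- c(msg, "dropoutMode must be fixed, bernoulli or none")
  for (v in c("corePrevalence", "backgroundPrevalence")) {
    x <- methods::slot(object, v)
    if (x < 0 || x > 1) msg <- c(msg, paste(v, "must be in [0, 1]"))
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "SimulationDesign", function(object) {
  cat("SimulationDesign:", nrow(object@groups), "groups,",
      sum(object@groups$n_replicates), "samples; effect =", object@effectSize,
      "; depth ~ logN(", object@depthMean, ",", object@depthDispersion, ")\n")
  invisible(object)
})

#' @rdname SimulationDesign-class
#' @param groups,depth_mean,depth_dispersion,core_spec,host_specific_spec,effect_size,core_prevalence,background_prevalence,core_boost,dropout_mode,seed see slots
#' @export
simulationDesign <- function(groups, depth_mean = 10000, depth_dispersion = 0.3,
                             core_spec = list(), host_specific_spec = list(),
                             effect_size = 1, core_prevalence = 0.95,
                             background_prevalence = 0.75, core_boost = 2.5,
                             dropout_mode = "fixed", seed = 1L) {
  methods::new("SimulationDesign", groups = as.data.frame(groups),
    depthMean = depth_mean, depthDispersion = depth_dispersion,
    coreSpec = core_spec, hostSpecificSpec = host_specific_spec,
    effectSize = effect_size, corePrevalence = core_prevalence,
    backgroundPrevalence = background_prevalence, coreBoost = core_boost,
    dropoutMode = dropout_mode, seed = as.integer(seed))
}

.feature_ids <- function(p) sprintf("ASV_%04d", seq_len(p))

#' The default study layout
#'
#' Builds the [SimulationDesign-class] emulating the mesocosm layout the
#' package targets: three seaweed hosts, each sampled on its own biofilm and
#' on a paired proxy-biofilm membrane, plus control filters and ambient
#' seawater, at two timepoints with `n_replicates` replicates (controls and
#' seawater included). Per host, `n_core` features are planted as the shared
#' core of its biofilm and proxy-biofilm groups and `n_host_specific`
#' features as strictly host-specific taxa; all planted sets are disjoint.
#'
#' @param n_features total number of features the paired graph will carry.
#' @param n_replicates replicates per group and timepoint.
#' @param n_core planted core features per host.
#' @param n_host_specific planted host-specific features per host.
#' @param hosts host treatment labels.
#' @param ... passed on to [simulationDesign()].
#' @return a `SimulationDesign`.
#' @export
studyDesign <- function(n_features = 120, n_replicates = 6, n_core = 6,
                        n_host_specific = 2,
                        hosts = c("F_serratus", "F_vesiculosus", "G_vermiculophylla"),
                        ...) {
  grid <- expand.grid(timepoint = c("exp1", "exp2"), substrate = c("seaweed", "proxy_biofilm"),
                      treatment = hosts, stringsAsFactors = FALSE)[, 3:1]
  ctrl <- expand.grid(timepoint = c("exp1", "exp2"),
                      substrate = c("control_filter", "seawater"),
                      treatment = "control", stringsAsFactors = FALSE)[, 3:1]
  groups <- rbind(grid, ctrl)
  groups$n_replicates <- ifelse(groups$substrate == "seawater",
                                max(2L, n_replicates %/% 2L), n_replicates)
  ids <- .feature_ids(n_features)
  per_host <- n_core + n_host_specific
  if (per_host * length(hosts) > n_features)
    stop("n_features too small for the planted core/host-specific sets")
  core_spec <- list(); hs_spec <- list()
  for (i in seq_along(hosts)) {
    block <- ids[((i - 1) * per_host + 1):(i * per_host)]
    core <- block[seq_len(n_core)]
    hs <- block[n_core + seq_len(n_host_specific)]
    core_spec[[paste(hosts[i], "seaweed", sep = "|")]] <- core
    core_spec[[paste(hosts[i], "proxy_biofilm", sep = "|")]] <- core
    hs_spec[[hosts[i]]] <- hs
  }
  simulationDesign(groups, core_spec = core_spec, host_specific_spec = hs_spec, ...)
}

#' A two-group null design
#'
#' Two exchangeable groups with identical specs, no planted structure, no
#' structural dropout and zero effect size — samples are iid under the null,
#' as permutation-test calibration requires.
#'
#' @param n_per_group samples per group.
#' @param depth_mean mean sequencing depth.
#' @param seed RNG seed.
#' @return a `SimulationDesign`.
#' @export
nullDesign <- function(n_per_group = 6, depth_mean = 5000, seed = 1L) {
  groups <- data.frame(treatment = c("A", "B"), substrate = "seaweed",
                       timepoint = "exp1", n_replicates = n_per_group)
  simulationDesign(groups, depth_mean = depth_mean, effect_size = 0,
                   dropout_mode = "none", seed = seed)
}

#' A single-group design for network-recovery experiments
#'
#' One homogeneous group of `n` samples with no planted structure or
#' dropout, so the only dependence between features is the ground-truth
#' association graph.
#'
#' @param n number of samples.
#' @param depth_mean mean sequencing depth.
#' @param seed RNG seed.
#' @return a `SimulationDesign`.
#' @export
singleGroupDesign <- function(n = 100, depth_mean = 10000, seed = 1L) {
  groups <- data.frame(treatment = "A", substrate = "seaweed",
                       timepoint = "exp1", n_replicates = n)
  simulationDesign(groups, depth_mean = depth_mean, effect_size = 0,
                   dropout_mode = "none", seed = seed)
}

#' Generate a ground-truth association graph
#'
#' Builds a sparse signed conditional-dependence graph and the precision
#' matrix implied by it. Edge values (partial correlations) are drawn
#' uniformly in `value_range` with random sign. The precision matrix has
#' unit diagonal and `-value` off-diagonals, so each edge's realised
#' partial correlation equals its drawn value; if a row would break strict
#' diagonal dominance (possible for dense topologies) all off-diagonals
#' are shrunk uniformly just enough to restore it, keeping the matrix
#' positive definite.
#'
#' Topologies: `band` (pairs closest on the index line first — bandwidth-1
#' band = chain), `cluster` (edges preferentially within `n_blocks` equal
#' blocks, 9:1 odds), `scale_free` (preferential attachment, extra/surplus
#' edges adjusted to hit the target count), `hub` (a few hub nodes carry
#' nearly all edges).
#'
#' @param n_features number of nodes (>= 3).
#' @param topology `"band"`, `"cluster"`, `"scale_free"` or `"hub"`.
#' @param density fraction of the `choose(n, 2)` possible edges, in \[0, 1).
#' @param seed RNG seed.
#' @param n_blocks number of blocks for the cluster topology.
#' @param value_range magnitude range for edge values.
#' @return a [GroundTruthGraph-class].
#' @export
makeGraph <- function(n_features, topology = c("band", "cluster", "scale_free", "hub"),
                      density = 0.04, seed = 1L, n_blocks = 2,
                      value_range = c(0.15, 0.35)) {
  topology <- match.arg(topology)
  p <- as.integer(n_features)
  if (p < 3) stop("n_features must be >= 3")
  if (density < 0 || density >= 1) stop("density must be in [0, 1)")
  n_pairs <- choose(p, 2)
  m <- round(density * n_pairs)
  set.seed(as.integer(seed))
  pairs <- NULL
  if (m > 0) {
    pairs <- switch(topology,
      band = {
        all_pairs <- t(utils::combn(p, 2))
        ord <- order(all_pairs[, 2] - all_pairs[, 1], all_pairs[, 1])
        all_pairs[ord[seq_len(m)], , drop = FALSE]
      },
      cluster = {
        blocks <- sort(rep_len(seq_len(n_blocks), p))
        all_pairs <- t(utils::combn(p, 2))
        within <- blocks[all_pairs[, 1]] == blocks[all_pairs[, 2]]
        w <- ifelse(within, 9, 1)
        idx <- sample(nrow(all_pairs), m, prob = w)
        all_pairs[idx, , drop = FALSE]
      },
      scale_free = {
        g <- igraph::sample_pa(p, power = 1, m = 1, directed = FALSE)
        el <- igraph::as_edgelist(g)
        el <- cbind(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
        if (nrow(el) > m) el <- el[sample(nrow(el), m), , drop = FALSE]
        while (nrow(el) < m) {   # grow preferentially to the target count
          deg <- tabulate(c(el), p) + 1
          cand <- sample(p, 2, prob = deg)
          cand <- c(min(cand), max(cand))
          if (cand[1] != cand[2] &&
              !any(el[, 1] == cand[1] & el[, 2] == cand[2]))
            el <- rbind(el, cand)
        }
        el
      },
      hub = {
        n_hub <- max(1L, ceiling(p / 10))
        hubs <- seq_len(n_hub)
        others <- setdiff(seq_len(p), hubs)
        el <- cbind(sample(hubs, length(others), replace = TRUE), others)
        el <- cbind(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
        if (nrow(el) > m) el <- el[sample(nrow(el), m), , drop = FALSE]
        while (nrow(el) < m) {
          cand <- c(sample(hubs, 1), sample(others, 1))
          cand <- c(min(cand), max(cand))
          if (!any(el[, 1] == cand[1] & el[, 2] == cand[2])) el <- rbind(el, cand)
        }
        el
      })
    pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  }
  m_eff <- if (is.null(pairs)) 0L else nrow(pairs)
  vals <- if (m_eff) stats::runif(m_eff, value_range[1], value_range[2]) *
                     sample(c(-1, 1), m_eff, replace = TRUE) else numeric()
  edges <- data.frame(from = if (m_eff) pairs[, 1] else integer(),
                      to = if (m_eff) pairs[, 2] else integer(),
                      value = vals)
  # Unit diagonal with omega_ij = -value makes the realised partial
  # correlation equal the drawn edge value; if any row breaks strict
  # diagonal dominance (dense topologies), all off-diagonals are shrunk
  # uniformly just enough to restore it, preserving the graph and signs.
  omega <- matrix(0, p, p)
  if (m_eff) {
    omega[cbind(edges$from, edges$to)] <- -edges$value
    omega <- omega + t(omega)
    rmax <- max(rowSums(abs(omega)))
    if (rmax >= 1) omega <- omega * (0.95 / rmax)
  }
  diag(omega) <- 1
  methods::new("GroundTruthGraph", nFeatures = p, edges = edges,
               topology = topology, precision = omega)
}

#' Ground-truth edge set
#'
#' The exact simulated edges of a [GroundTruthGraph-class], keyed by the
#' feature IDs [simulateCounts()] assigns (`ASV_0001`, ...), for
#' precision/recall scoring of inferred networks.
#'
#' @param g a `GroundTruthGraph`.
#' @return data.frame(from, to, sign) with `from < to` in feature-ID order.
#' @export
truthEdgeSet <- function(g) {
  ids <- .feature_ids(g@nFeatures)
  e <- g@edges
  data.frame(from = ids[e$from], to = ids[e$to],
             sign = ifelse(e$value > 0, "+", "-"),
             stringsAsFactors = FALSE)
}

.group_label <- function(treatment, substrate) paste(treatment, substrate, sep = "|")

#' Planted ground truth for core / host-specific extraction
#'
#' `expectedCore` returns the features planted to satisfy the core
#' definition in a group: the group's `coreSpec` entry plus, for host
#' biofilm and proxy-biofilm groups, the host's host-specific features
#' (structurally present in every sample of those groups, hence core
#' members by definition). `expectedHostSpecific` returns the planted
#' host-specific set.
#'
#' @param design a [SimulationDesign-class].
#' @param group group label `treatment|substrate`.
#' @param host host treatment label.
#' @return sorted character vector of feature IDs.
#' @export
expectedCore <- function(design, group) {
  parts <- strsplit(group, "|", fixed = TRUE)[[1]]
  out <- design@coreSpec[[group]]
  if (length(parts) == 2 && parts[2] %in% c("seaweed", "proxy_biofilm"))
    out <- union(out, design@hostSpecificSpec[[parts[1]]])
  sort(out)
}

#' @rdname expectedCore
#' @export
expectedHostSpecific <- function(design, host)
  sort(design@hostSpecificSpec[[host]] %||% character())

#' Simulate grouped compositional count data with known structure
#'
#' Logistic-normal-multinomial generator. Latent log-abundances are drawn
#' multivariate normal with covariance equal to the correlation matrix of
#' the inverse of the graph's precision matrix; treatment effects enter as
#' log-scale mean shifts, while planted core and host-specific features
#' take a fixed elevated group mean (`coreBoost`) inside their groups so
#' that planting guarantees consistent detectability; the
#' latent vector is exponentiated and closed to a composition; structural
#' zeros (host-specific absence, prevalence dropout) are applied to the
#' composition *before* the multinomial draw, so absences are guaranteed
#' while each sample's total still equals its drawn log-normal depth
#' exactly. A fixed seed gives bit-identical output.
#'
#' @param graph a [GroundTruthGraph-class] from [makeGraph()].
#' @param design a [SimulationDesign-class].
#' @param seed RNG seed; defaults to the design's seed.
#' @return a [BiofilmExperiment-class] with sample metadata (`colData`:
#'   treatment, substrate, timepoint, panel, bottle) and feature taxonomy
#'   (`rowData`: domain_class, lineage, copy_number). The drawn depths equal
#'   `sampleTotals()` of the result.
#' @export
simulateCounts <- function(graph, design, seed = design@seed) {
  p <- graph@nFeatures
  ids <- .feature_ids(p)
  set.seed(as.integer(seed))
  groups <- design@groups
  meta <- .build_metadata(groups)
  n_samples <- nrow(meta)
  sigma <- stats::cov2cor(solve(graph@precision))
  mu0 <- stats::rnorm(p)
  treatments <- setdiff(unique(groups$treatment), "control")
  effect_feats <- lapply(treatments, function(tr)
    sample(p, size = max(1L, round(0.2 * p))))
  names(effect_feats) <- treatments

  latent <- matrix(0, n_samples, p)
  for (gi in seq_len(nrow(groups))) {
    rows <- which(meta$.group_row == gi)
    tr <- groups$treatment[gi]; sub <- groups$substrate[gi]
    mu <- mu0
    if (design@effectSize > 0 && tr %in% names(effect_feats))
      mu[effect_feats[[tr]]] <- mu[effect_feats[[tr]]] + design@effectSize
    key <- .group_label(tr, sub)
    # planted features take a fixed elevated group mean (not baseline +
    # boost): "planted as core" must guarantee consistent detectability,
    # which the baseline log-mean lottery would otherwise undermine
    core <- match(design@coreSpec[[key]], ids)
    if (length(core)) mu[core] <- design@coreBoost
    if (tr %in% names(design@hostSpecificSpec) &&
        sub %in% c("seaweed", "proxy_biofilm")) {
      hs <- match(design@hostSpecificSpec[[tr]], ids)
      mu[hs] <- design@coreBoost
    }
    latent[rows, ] <- MASS::mvrnorm(length(rows), mu, sigma)
  }

  w <- exp(latent)
  # host-specific features are structurally absent outside host + host-PB
  for (h in names(design@hostSpecificSpec)) {
    hs <- match(design@hostSpecificSpec[[h]], ids)
    outside <- !(meta$treatment == h & meta$substrate %in% c("seaweed", "proxy_biofilm"))
    w[outside, hs] <- 0
  }
  # structural prevalence dropout, per pooled group (treatment x substrate)
  if (design@dropoutMode != "none") {
    pooled <- .group_label(meta$treatment, meta$substrate)
    for (key in unique(pooled)) {
      rows <- which(pooled == key)
      tr <- meta$treatment[rows[1]]
      hs <- if (tr %in% names(design@hostSpecificSpec))
        match(design@hostSpecificSpec[[tr]], ids) else integer()
      core <- match(design@coreSpec[[key]], ids)
      for (f in seq_len(p)) {
        if (f %in% hs) next
        prev <- if (f %in% core) design@corePrevalence else design@backgroundPrevalence
        drop_rows <- if (design@dropoutMode == "fixed") {
          n_drop <- floor((1 - prev) * length(rows))
          if (n_drop > 0) sample(rows, n_drop) else integer()
        } else rows[stats::runif(length(rows)) > prev]
        w[drop_rows, f] <- 0
      }
    }
  }

  depths <- pmax(1, round(stats::rlnorm(n_samples, log(design@depthMean),
                                        design@depthDispersion)))
  cnt <- matrix(0L, p, n_samples, dimnames = list(ids, meta$sample_id))
  for (s in seq_len(n_samples)) {
    ws <- w[s, ]
    if (all(ws == 0)) stop("sample with empty composition; check dropout settings")
    cnt[, s] <- stats::rmultinom(1, depths[s], ws / sum(ws))
  }
  tax <- .build_taxonomy(ids)
  meta$.group_row <- NULL
  BiofilmExperiment(cnt, sampleData = meta, taxonomy = tax)
}

.build_metadata <- function(groups) {
  out <- list()
  for (gi in seq_len(nrow(groups))) {
    g <- groups[gi, ]
    reps <- seq_len(g$n_replicates)
    out[[gi]] <- data.frame(
      sample_id = sprintf("%s_%s_%s_r%02d", g$treatment, g$substrate, g$timepoint, reps),
      treatment = g$treatment, substrate = g$substrate, timepoint = g$timepoint,
      # panel/bottle block structure is stable across timepoints by construction
      panel = sprintf("panel_%02d", ((reps - 1) %% 12) + 1),
      bottle = sprintf("bottle_%s_%02d", g$treatment, reps),
      .group_row = gi, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

.build_taxonomy <- function(ids) {
  p <- length(ids)
  n_alga <- max(1L, round(0.15 * p))
  domain <- rep("prokaryote", p)
  domain[(p - n_alga + 1):p] <- "microalga"
  phyla_pro <- c("Proteobacteria", "Bacteroidota", "Actinobacteriota",
                 "Verrucomicrobiota", "Planctomycetota")
  phyla_alg <- c("Bacillariophyta", "Chlorophyta", "Cryptophyta")
  lineage <- ifelse(domain == "prokaryote",
    paste("Bacteria", sample(phyla_pro, p, replace = TRUE),
          ifelse(stats::runif(p) < 0.2, "Unassigned", sprintf("Genus_%03d", sample(200, p, TRUE))),
          sep = ";"),
    paste("Eukaryota", sample(phyla_alg, p, replace = TRUE),
          sprintf("Genus_%03d", sample(200, p, TRUE)), sep = ";"))
  copy_number <- ifelse(domain == "prokaryote", sample(1:10, p, replace = TRUE), NA_real_)
  data.frame(feature_id = ids, domain_class = domain, lineage = lineage,
             copy_number = copy_number, stringsAsFactors = FALSE)
}

#' Write a simulated dataset to disk
#'
#' Convenience writer used by the pipeline's `simulate` stage: count table
#' (TSV), sample metadata, taxonomy, and the ground-truth edge list
#' (`feature_a`, `feature_b`, `sign`, `value`).
#'
#' @param x a `BiofilmExperiment` from [simulateCounts()].
#' @param graph the `GroundTruthGraph` used.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeSimulation <- function(x, graph, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("counts.tsv", "metadata.tsv", "taxonomy.tsv", "truth_edges.tsv"))
  writeCountTable(x, paths[1], "tsv")
  meta <- as.data.frame(SummarizedExperiment::colData(x))
  meta <- cbind(sample_id = rownames(meta), meta)
  utils::write.table(meta, paths[2], sep = "\t", quote = FALSE, row.names = FALSE)
  tax <- as.data.frame(SummarizedExperiment::rowData(x))
  tax <- cbind(feature_id = rownames(tax), tax)
  utils::write.table(tax, paths[3], sep = "\t", quote = FALSE, row.names = FALSE)
  te <- truthEdgeSet(graph)
  ids <- .feature_ids(graph@nFeatures)
  te$value <- graph@edges$value
  names(te)[1:2] <- c("feature_a", "feature_b")
  utils::write.table(te, paths[4], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
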