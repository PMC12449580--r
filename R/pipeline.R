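#' Read and validate a pipeline configuration
#'
#' YAML configuration with one block per stage. Either a `simulate` block
#' (synthetic data with known ground truth) or an `input` block (paths to
#' counts/metadata/taxonomy TSVs) must be present; every threshold is
#' checked against its valid range at load. Defaults mirror the package's
#' standard analysis values: depth filter 2000 (prokaryotes) / 100
#' (microalgae), core detection > 3 reads at >= 90% prevalence and
#' >= 0.001% mean relative abundance, WMC filter at 0.25% abundance,
#' 999 permutations, StARS instability threshold 0.05.
#'
#' @param path path to a YAML config file.
#' @return a validated named list (class `phyconet_config`).
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(
    seed = 1L,
    filter = list(min_depth = 100),
    core = list(min_reads = 3, min_prevalence = 0.9, min_abundance_fraction = 1e-5),
    stats = list(factor = "substrate", n_perm = 999, pairwise = TRUE),
    network = list(level = "wmc", min_total_reads = 3, min_mean_rel_abund = 0.0025,
                   n_lambda = 20, lambda_min_ratio = 0.01, n_subsamples = 10,
                   beta_threshold = 0.05, rule = "or", pseudocount = 1,
                   min_group_size = 5),
    metrics = list(z_thresh = 2.5, p_thresh = 0.62, n_restarts = 10),
    netcompare = list(standardize = "zscore"))
  for (nm in names(defaults)) {
    if (is.list(defaults[[nm]])) {
      cfg[[nm]] <- utils::modifyList(defaults[[nm]], if (is.null(cfg[[nm]])) list() else cfg[[nm]])
    } else if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  }
  if (is.null(cfg$simulate) && is.null(cfg$input))
    stop("config needs a 'simulate' or an 'input' block")
  .check_range <- function(x, lo, hi, what) {
    if (!is.numeric(x) || x < lo || x > hi)
      stop("config: ", what, " must be in [", lo, ", ", hi, "]")
  }
  .check_range(cfg$filter$min_depth, 1, Inf, "filter.min_depth")
  .check_range(cfg$core$min_reads, 0, Inf, "core.min_reads")
  .check_range(cfg$core$min_prevalence, 0, 1, "core.min_prevalence")
  .check_range(cfg$core$min_abundance_fraction, 0, 1, "core.min_abundance_fraction")
  .check_range(cfg$stats$n_perm, 1, Inf, "stats.n_perm")
  .check_range(cfg$network$min_mean_rel_abund, 0, 1, "network.min_mean_rel_abund")
  .check_range(cfg$network$beta_threshold, 0, 0.5, "network.beta_threshold")
  if (!cfg$network$rule %in% c("or", "and")) stop("config: network.rule must be or/and")
  .check_range(cfg$metrics$p_thresh, 0, 1, "metrics.p_thresh")
  if (!is.null(cfg$input))
    for (f in unlist(cfg$input))
      if (!file.exists(f)) stop("config: input path does not exist: ", f)
  class(cfg) <- c("phyconet_config", "list")
  cfg
}

# Per-stage seed: a polynomial hash of the stage name mixed with the master
# seed, so adding a stage never perturbs the randomness of earlier stages.
.stage_seed <- function(master, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 1000003
  as.integer((as.numeric(master) * 7919 + h) %% 2147480000)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes, in order: `simulate` (or load), `filter`, `core`, `stats`,
#' `network`, `metrics`, `netcompare`, writing each stage's outputs under
#' `output_dir/<stage>/` and a `manifest.json` (package version, config
#' hash, per-stage seeds and runtimes). The same config and seed give
#' byte-identical stage outputs; a stage failure aborts with an error naming
#' the stage, retaining the outputs already written.
#'
#' @param config a `phyconet_config` from [readPipelineConfig()], or a path
#'   to a YAML config.
#' @param output_dir output directory (default from the config).
#' @return invisibly, the manifest list.
#' @export
runPipeline <- function(config, output_dir = NULL) {
  if (is.character(config)) {
    config_path <- config
    config <- readPipelineConfig(config)
  } else config_path <- NULL
  out <- output_dir %||% config$output_dir
  if (is.null(out)) stop("no output directory given")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  master <- as.integer(config$seed)
  manifest <- list(package = "phyconet",
                   version = as.character(utils::packageVersion("phyconet")),
                   config_hash = if (!is.null(config_path))
                     unname(tools::md5sum(config_path)) else NA_character_,
                   master_seed = master, stages = list())
  state <- new.env(parent = emptyenv())
  stage_names <- c("simulate", "filter", "core", "stats", "network",
                   "metrics", "netcompare")
  for (stage in stage_names) {
    seed <- .stage_seed(master, stage)
    t0 <- proc.time()[["elapsed"]]
    ok <- tryCatch({
      get(paste0(".stage_", stage))(config, state, out, seed)
      TRUE
    }, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
    manifest$stages[[stage]] <- list(seed = seed,
      runtime_s = round(proc.time()[["elapsed"]] - t0, 3))
  }
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.stage_simulate <- function(cfg, state, out, seed) {
  dir <- file.path(out, "simulate")
  if (!is.null(cfg$input)) {
    x <- readCountTable(cfg$input$counts, cfg$input$format %||% "tsv")
    x <- attachAnnotation(x,
      sampleData = readSampleMetadata(cfg$input$metadata),
      taxonomy = if (!is.null(cfg$input$taxonomy)) readTaxonomy(cfg$input$taxonomy))
    state$truth <- NULL
    state$x <- x
    return(invisible())
  }
  sc <- cfg$simulate
  graph <- makeGraph(sc$n_features %||% 60, sc$topology %||% "band",
                     sc$density %||% 0.04, seed = seed)
  design <- studyDesign(n_features = sc$n_features %||% 60,
                        n_replicates = sc$n_replicates %||% 6,
                        n_core = sc$n_core %||% 4,
                        n_host_specific = sc$n_host_specific %||% 2,
                        depth_mean = sc$depth_mean %||% 10000,
                        effect_size = sc$effect_size %||% 1,
                        seed = seed)
  x <- simulateCounts(graph, design, seed = seed)
  writeSimulation(x, graph, dir)
  state$x <- x
  state$graph <- graph
  state$design <- design
  state$truth <- truthEdgeSet(graph)
}

.stage_filter <- function(cfg, state, out, seed) {
  dir <- file.path(out, "filter"); dir.create(dir, showWarnings = FALSE)
  x <- filterMinDepth(state$x, cfg$filter$min_depth)
  writeCountTable(x, file.path(dir, "filtered_counts.tsv"))
  state$x <- x
}

.stage_core <- function(cfg, state, out, seed) {
  dir <- file.path(out, "core"); dir.create(dir, showWarnings = FALSE)
  x <- state$x
  cc <- cfg$core
  groups <- sort(unique(sampleGroups(x)))
  groups <- groups[vapply(groups, function(g)
    length(.group_samples(x, g)) >= 2, logical(1))]
  cores <- lapply(groups, function(g)
    extractCore(x, g, min_reads = cc$min_reads,
                min_prevalence = cc$min_prevalence,
                min_abundance_fraction = cc$min_abundance_fraction))
  ct <- coreTable(cores)
  if (is.null(ct)) ct <- data.frame(group = character(), feature_id = character(),
                                    prevalence = numeric(), mean_rel_abundance = numeric())
  .write_tsv(ct, file.path(dir, "core_sets.tsv"))
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  hosts <- setdiff(unique(cd$treatment[cd$substrate %in% c("seaweed", "proxy_biofilm")]),
                   "control")
  hs <- list()
  if (all(c("control_filter", "seawater") %in% cd$substrate)) {
    hs <- lapply(hosts, function(h) extractHostSpecific(x, h))
    hst <- do.call(rbind, lapply(hs, function(s)
      if (length(s@features)) data.frame(host = s@host, feature_id = s@features)))
    if (is.null(hst)) hst <- data.frame(host = character(), feature_id = character())
    .write_tsv(hst, file.path(dir, "host_specific.tsv"))
  }
  state$cores <- cores
  state$host_specific <- hs
}

.stage_stats <- function(cfg, state, out, seed) {
  dir <- file.path(out, "stats"); dir.create(dir, showWarnings = FALSE)
  x <- state$x
  sc <- cfg$stats
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  fac <- cd[[sc$factor]]
  if (is.null(fac)) stop("stats factor '", sc$factor, "' not in metadata")
  sh <- data.frame(sample_id = colnames(x), shannon = unname(shannonIndex(x)))
  .write_tsv(sh, file.path(dir, "shannon.tsv"))
  d <- brayCurtis(x)
  .write_tsv(data.frame(sample_id = rownames(d), round(d, 10), check.names = FALSE),
             file.path(dir, "bray_curtis.tsv"))
  pm <- permanovaTest(d, fac, n_perm = sc$n_perm, seed = seed)
  pm$factor <- sc$factor
  bd <- betaDispersion(d, fac, n_perm = sc$n_perm, seed = seed)
  bd$factor <- sc$factor
  .write_tsv(rbind(cbind(test = "permanova", pm), cbind(test = "beta_dispersion", bd)),
             file.path(dir, "permanova.tsv"))
  if (isTRUE(sc$pairwise)) {
    pw <- pairwisePermanova(d, fac, n_perm = sc$n_perm, seed = seed)
    .write_tsv(pw, file.path(dir, "pairwise_permanova.tsv"))
  }
  ord <- pcoaOrdination(d, n_axes = min(3, nrow(d) - 1))
  .write_tsv(data.frame(sample_id = rownames(ord$coordinates),
                        round(ord$coordinates, 10), check.names = FALSE),
             file.path(dir, "pcoa_coordinates.tsv"))
  state$dist <- d
}

.stage_network <- function(cfg, state, out, seed) {
  dir <- file.path(out, "network"); dir.create(dir, showWarnings = FALSE)
  x <- state$x
  nc <- cfg$network
  groups <- nc$groups
  if (is.null(groups)) {
    all_groups <- sort(unique(sampleGroups(x)))
    groups <- all_groups[vapply(all_groups, function(g)
      length(.group_samples(x, g)) >= nc$min_group_size, logical(1))]
  }
  if (!length(groups)) stop("no groups to build networks for")
  nets <- list()
  for (g in groups) {
    ss <- .group_samples(x, g)
    if (!length(ss)) stop("empty group '", g, "'")
    sub <- x[, ss]
    sub <- if (identical(nc$level, "core")) {
      core <- extractCore(x, g, min_reads = cfg$core$min_reads,
                          min_prevalence = cfg$core$min_prevalence,
                          min_abundance_fraction = cfg$core$min_abundance_fraction)
      if (length(core@features) < 3) stop("core of '", g, "' too small for a network")
      sub[core@features, ]
    } else wmcFilter(sub, nc$min_total_reads, nc$min_mean_rel_abund)
    nets[[g]] <- inferNetwork(sub, pseudocount = nc$pseudocount,
                              n_lambda = nc$n_lambda,
                              lambda_min_ratio = nc$lambda_min_ratio,
                              n_subsamples = nc$n_subsamples,
                              beta_threshold = nc$beta_threshold,
                              rule = nc$rule, seed = .stage_seed(seed, g))
    writeNetwork(nets[[g]], file.path(dir, gsub("[^A-Za-z0-9_]", "_", g)))
  }
  state$networks <- nets
}

.stage_metrics <- function(cfg, state, out, seed) {
  dir <- file.path(out, "metrics"); dir.create(dir, showWarnings = FALSE)
  mc <- cfg$metrics
  profiles <- list()
  for (g in names(state$networks)) {
    net <- state$networks[[g]]
    part <- detectModules(net, n_restarts = mc$n_restarts, seed = .stage_seed(seed, g))
    roles <- ziPi(net, part, z_thresh = mc$z_thresh, p_thresh = mc$p_thresh)
    .write_tsv(roles, file.path(dir, paste0("roles_", gsub("[^A-Za-z0-9_]", "_", g), ".tsv")))
    profiles[[g]] <- networkProfile(net, n_restarts = mc$n_restarts,
                                    seed = .stage_seed(seed, g))
  }
  pm <- do.call(rbind, profiles)
  .write_tsv(data.frame(network = rownames(pm), round(pm, 10), check.names = FALSE),
             file.path(dir, "network_profiles.tsv"))
  state$profiles <- profiles
}

.stage_netcompare <- function(cfg, state, out, seed) {
  dir <- file.path(out, "netcompare"); dir.create(dir, showWarnings = FALSE)
  profs <- state$profiles
  if (length(profs) < 2) {
    .write_tsv(data.frame(note = "fewer than 2 networks; nothing to compare"),
               file.path(dir, "profile_distance.tsv"))
    return(invisible())
  }
  std <- cfg$netcompare$standardize
  pd <- suppressWarnings(profileDistance(profs, standardize = std))
  .write_tsv(data.frame(network = rownames(pd), round(pd, 10), check.names = FALSE),
             file.path(dir, "profile_distance.tsv"))
  if (length(profs) >= 3) {
    pca <- suppressWarnings(profilePCA(profs, standardize = std))
    .write_tsv(data.frame(network = rownames(pca$coordinates),
                          round(pca$coordinates, 10), check.names = FALSE),
               file.path(dir, "pca_coordinates.tsv"))
  }
  pairs <- utils::combn(names(profs), 2)
  ss <- lapply(seq_len(ncol(pairs)), function(j) {
    s <- sharedStructure(state$networks[[pairs[1, j]]], state$networks[[pairs[2, j]]])
    data.frame(network1 = pairs[1, j], network2 = pairs[2, j],
               shared_nodes = s$n_nodes, shared_edges = s$n_edges)
  })
  .write_tsv(do.call(rbind, ss), file.path(dir, "shared_structure.tsv"))
}
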