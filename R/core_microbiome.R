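#' Detection prevalence of a feature
#'
#' Fraction of samples in which the feature exceeds `detection_min_reads`
#' reads. The read boundary is strict (`count > detection_min_reads`,
#' i.e. "more than 3 sequence reads" with the default), matching the core
#' definition; the prevalence boundary applied by [extractCore()] is
#' inclusive.
#'
#' @param x a `BiofilmExperiment` (optionally subset to a group).
#' @param feature feature ID (or vector of IDs).
#' @param detection_min_reads strict read threshold (default 3).
#' @return named numeric in \[0, 1\], one value per feature.
#' @export
featurePrevalence <- function(x, feature = rownames(x), detection_min_reads = 3) {
  m <- counts(x)
  missing <- setdiff(feature, rownames(m))
  if (length(missing)) stop("unknown feature(s): ", paste(missing, collapse = ", "))
  rowMeans(m[feature, , drop = FALSE] > detection_min_reads)
}

.group_samples <- function(x, group, group_by = c("treatment", "substrate")) {
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  miss <- setdiff(group_by, names(cd))
  if (length(miss)) stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
  labels <- do.call(paste, c(cd[group_by], sep = "|"))
  colnames(x)[labels == group]
}

#' Group labels of the samples
#'
#' @param x a `BiofilmExperiment`.
#' @param group_by metadata columns whose combination defines a group
#'   (default pools timepoints: `treatment|substrate`).
#' @return character vector of labels, one per sample.
#' @export
sampleGroups <- function(x, group_by = c("treatment", "substrate")) {
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  do.call(paste, c(cd[group_by], sep = "|"))
}

#' Extract a group's compositional core
#'
#' Core members of a sample group are the features detected with more than
#' `min_reads` reads in at least `min_prevalence` of the group's samples
#' (prevalence boundary inclusive, read boundary strict) whose group-level
#' mean relative abundance is at least `min_abundance_fraction` (default
#' 0.001% = 1e-5 — deliberately low, to keep rare but persistent taxa).
#' Prevalence is pooled across timepoints by default; pass
#' `group_by = c("treatment", "substrate", "timepoint")` for per-timepoint
#' cores.
#'
#' @param x a `BiofilmExperiment` with sample metadata.
#' @param group group label, e.g. `"F_serratus|seaweed"`.
#' @param min_reads strict detection read threshold.
#' @param min_prevalence inclusive prevalence threshold.
#' @param min_abundance_fraction inclusive mean relative-abundance threshold.
#' @param group_by metadata columns defining the groups.
#' @return a [CoreSet-class].
#' @export
extractCore <- function(x, group, min_reads = 3, min_prevalence = 0.9,
                        min_abundance_fraction = 1e-5,
                        group_by = c("treatment", "substrate")) {
  ss <- .group_samples(x, group, group_by)
  if (length(ss) < 2) stop("group '", group, "' has fewer than 2 samples")
  sub <- x[, ss]
  prev <- featurePrevalence(sub, detection_min_reads = min_reads)
  mra <- rowMeans(relAbundance(sub))
  keep <- prev >= min_prevalence & mra >= min_abundance_fraction
  stats <- data.frame(feature_id = rownames(sub), prevalence = unname(prev),
                      mean_rel_abundance = unname(mra), core = unname(keep),
                      stringsAsFactors = FALSE)
  methods::new("CoreSet", group = group, features = rownames(sub)[keep],
    params = list(min_reads = min_reads, min_prevalence = min_prevalence,
                  min_abundance_fraction = min_abundance_fraction),
    stats = stats)
}

#' Extract host-specific taxa
#'
#' Features present (count above `detection`) in *every* sample of the host
#' biofilm and its paired proxy-biofilm group across both timepoints, and
#' absent (count at or below `detection`) from every control-filter and
#' seawater sample. The default `detection = 0` reads presence as any read
#' at all.
#'
#' @param x a `BiofilmExperiment` with sample metadata.
#' @param host host treatment label.
#' @param detection presence threshold (strict `>`; default 0).
#' @param host_substrates substrates forming the presence set.
#' @param excluded_substrates substrates forming the absence set.
#' @return a [HostSpecificSet-class].
#' @export
extractHostSpecific <- function(x, host, detection = 0,
                                host_substrates = c("seaweed", "proxy_biofilm"),
                                excluded_substrates = c("control_filter", "seawater")) {
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  in_host <- cd$treatment == host & cd$substrate %in% host_substrates
  in_excl <- cd$substrate %in% excluded_substrates
  for (sub in host_substrates)
    for (tp in unique(cd$timepoint))
      if (!any(in_host & cd$substrate == sub & cd$timepoint == tp))
        stop("missing ", host, "/", sub, " samples at ", tp)
  if (!any(in_excl)) stop("no control/seawater samples present")
  m <- counts(x)
  present_all <- rowSums(m[, in_host, drop = FALSE] <= detection) == 0
  absent_all <- rowSums(m[, in_excl, drop = FALSE] > detection) == 0
  methods::new("HostSpecificSet", host = host,
    features = rownames(m)[present_all & absent_all],
    excludedGroups = unique(sampleGroups(x)[in_excl]))
}

#' Tabulate core sets for export
#'
#' @param cores list of [CoreSet-class] objects.
#' @return data.frame(group, feature_id, prevalence, mean_rel_abundance)
#'   restricted to core members.
#' @export
coreTable <- function(cores) {
  if (methods::is(cores, "CoreSet")) cores <- list(cores)
  do.call(rbind, lapply(cores, function(cs) {
    st <- cs@stats[cs@stats$core, c("feature_id", "prevalence", "mean_rel_abundance")]
    if (nrow(st)) cbind(group = cs@group, st, row.names = NULL)
  }))
}
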