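#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData colData rowData<- colData<-
NULL

#' BiofilmExperiment: ASV counts with sample metadata and feature taxonomy
#'
#' The central data container of the package. A thin extension of
#' [SummarizedExperiment::SummarizedExperiment] holding one `counts` assay
#' with features (ASVs) as rows and samples as columns, sample metadata as
#' `colData` (treatment, substrate, timepoint, panel, bottle) and feature
#' taxonomy as `rowData` (domain_class, lineage, copy_number).
#'
#' Validity requires unique feature and sample identifiers, finite
#' non-negative counts, and a positive total for every sample. Counts are
#' integer at construction from files; real-valued matrices (e.g. after
#' 16S gene-copy-number correction) are allowed and flow through downstream
#' operations unchanged.
#'
#' @slot .. see [SummarizedExperiment::SummarizedExperiment]
#' @export
setClass("BiofilmExperiment", contains = "SummarizedExperiment")

setValidity("BiofilmExperiment", function(object) {
  msg <- character()
  if (!"counts" %in% names(SummarizedExperiment::assays(object)))
    msg <- c(msg, "assay 'counts' is required")
  else {
    m <- SummarizedExperiment::assay(object, "counts")
    if (is.null(rownames(m)) || is.null(colnames(m)))
      msg <- c(msg, "counts must have feature (row) and sample (column) names")
    else {
      if (anyDuplicated(rownames(m))) msg <- c(msg, "duplicate feature IDs")
      if (anyDuplicated(colnames(m))) msg <- c(msg, "duplicate sample IDs")
    }
    if (any(!is.finite(m))) msg <- c(msg, "counts must be finite")
    else if (any(m < 0)) msg <- c(msg, "counts must be non-negative")
    if (ncol(m) > 0 && any(colSums(m) <= 0))
      msg <- c(msg, "every sample must have total > 0")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a BiofilmExperiment
#'
#' @param counts numeric matrix, features x samples, with dimnames.
#' @param sampleData `data.frame`/`DataFrame` of per-sample metadata, one row
#'   per column of `counts` (matched by row name or `sample_id` column).
#'   Expected columns when present: `treatment`, `substrate`, `timepoint`,
#'   `panel`, `bottle`.
#' @param taxonomy `data.frame`/`DataFrame` of per-feature annotation, one row
#'   per row of `counts` (matched by row name or `feature_id` column).
#'   Expected columns when present: `domain_class` (`"prokaryote"` or
#'   `"microalga"`), `lineage`, `copy_number`.
#' @return A [BiofilmExperiment-class] object.
#' @examples
#' m <- matrix(c(3L, 0L, 0L, 5L), 2, dimnames = list(c("f1", "f2"), c("s1", "s2")))
#' be <- BiofilmExperiment(m)
#' sampleTotals(be)
#' @export
BiofilmExperiment <- function(counts, sampleData = NULL, taxonomy = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- if (all(counts == round(counts))) "integer" else "double"
  cd <- .align_annotation(sampleData, colnames(counts), "sample_id")
  rd <- .align_annotation(taxonomy, rownames(counts), "feature_id")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = S4Vectors::SimpleList(counts = counts),
    colData = cd, rowData = rd)
  methods::new("BiofilmExperiment", se)
}

# Reorder an annotation table to match `ids`, using rownames or an id column.
.align_annotation <- function(df, ids, id_col) {
  if (is.null(df)) return(S4Vectors::DataFrame(row.names = ids))
  df <- as.data.frame(df)
  if (id_col %in% names(df)) {
    rownames(df) <- as.character(df[[id_col]])
    df[[id_col]] <- NULL
  }
  missing <- setdiff(ids, rownames(df))
  if (length(missing))
    stop("annotation missing entries for: ", paste(utils::head(missing, 5), collapse = ", "))
  S4Vectors::DataFrame(df[ids, , drop = FALSE], row.names = ids)
}

#' @describeIn BiofilmExperiment counts matrix (features x samples)
#' @param object,x a `BiofilmExperiment`
#' @export
setGeneric("counts", function(object, ...) standardGeneric("counts"))

#' @rdname BiofilmExperiment
#' @param ... unused
#' @export
setMethod("counts", "BiofilmExperiment", function(object, ...)
  SummarizedExperiment::assay(object, "counts"))

#' Per-sample read totals
#' @param x a `BiofilmExperiment`
#' @return named numeric vector of sample totals.
#' @export
sampleTotals <- function(x) colSums(counts(x))

#' Relative abundances
#'
#' Divides each sample (column) by its total.
#' @param x a `BiofilmExperiment` or a features x samples matrix.
#' @return features x samples matrix of relative abundances (columns sum to 1).
#' @export
relAbundance <- function(x) {
  m <- if (methods::is(x, "BiofilmExperiment")) counts(x) else as.matrix(x)
  sweep(m, 2L, colSums(m), "/")
}

setMethod("show", "BiofilmExperiment", function(object) {
  cat("BiofilmExperiment:", nrow(object), "features x", ncol(object), "samples\n")
  if ("domain_class" %in% names(SummarizedExperiment::rowData(object))) {
    tab <- table(SummarizedExperiment::rowData(object)$domain_class)
    cat("  features:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  if ("treatment" %in% names(SummarizedExperiment::colData(object))) {
    tab <- table(SummarizedExperiment::colData(object)$treatment)
    cat("  treatments:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  cat("  total reads:", sum(counts(object)), "\n")
  invisible(object)
})

#' Ground-truth association graph for simulation
#'
#' A sparse signed conditional-dependence graph over features together with
#' the positive-definite precision matrix built from it. Produced by
#' [makeGraph()]; consumed by [simulateCounts()] and scored against inferred
#' networks via [truthEdgeSet()].
#'
#' @slot nFeatures number of features (nodes).
#' @slot edges data.frame with columns `from`, `to` (integer node indices,
#'   `from < to`) and `value` (signed partial-correlation-scale entry).
#' @slot topology one of `"band"`, `"cluster"`, `"scale_free"`, `"hub"`.
#' @slot precision the symmetric positive-definite precision matrix.
#' @export
setClass("GroundTruthGraph",
  representation(nFeatures = "integer", edges = "data.frame",
                 topology = "character", precision = "matrix"))

setValidity("GroundTruthGraph", function(object) {
  msg <- character()
  e <- object@edges
  if (!all(c("from", "to", "value") %in% names(e)))
    msg <- c(msg, "edges needs columns from, to, value")
  else if (nrow(e)) {
    if (any(e$from >= e$to)) msg <- c(msg, "edges must have from < to (no self-edges)")
    if (any(e$to > object@nFeatures)) msg <- c(msg, "edge index out of range")
  }
  ev <- eigen(object@precision, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) msg <- c(msg, "precision matrix must be positive definite")
  if (length(msg)) msg else TRUE
})

setMethod("show", "GroundTruthGraph", function(object) {
  cat("GroundTruthGraph:", object@nFeatures, "features,",
      nrow(object@edges), "edges, topology =", object@topology, "\n")
  invisible(object)
})

#' Per-group compositional core
#'
#' Features of one sample group passing the prevalence / read-count /
#' mean-relative-abundance thresholds, with the thresholds recorded verbatim
#' and per-feature statistics for all candidate features.
#'
#' @slot group group label.
#' @slot features character vector of core member feature IDs.
#' @slot params list(min_reads, min_prevalence, min_abundance_fraction).
#' @slot stats data.frame(feature_id, prevalence, mean_rel_abundance) for the
#'   group's observed features.
#' @export
setClass("CoreSet",
  representation(group = "character", features = "character",
                 params = "list", stats = "data.frame"))

setMethod("show", "CoreSet", function(object) {
  cat("CoreSet [", object@group, "]: ", length(object@features),
      " features (min_reads > ", object@params$min_reads,
      ", prevalence >= ", object@params$min_prevalence,
      ", mean rel. abund. >= ", object@params$min_abundance_fraction, ")\n",
      sep = "")
  invisible(object)
})

#' Host-specific taxon set
#'
#' Features present in every sample of a host and its proxy-biofilm group
#' (both timepoints) and absent from all excluded groups (control filters,
#' seawater).
#'
#' @slot host host (treatment) label.
#' @slot features character vector of feature IDs.
#' @slot excludedGroups labels of the absence groups.
#' @export
setClass("HostSpecificSet",
  representation(host = "character", features = "character",
                 excludedGroups = "character"))

setMethod("show", "HostSpecificSet", function(object) {
  cat("HostSpecificSet [", object@host, "]: ", length(object@features),
      " features absent from {", paste(object@excludedGroups, collapse = ", "),
      "}\n", sep = "")
  invisible(object)
})

#' Signed weighted association network
#'
#' Undirected signed weighted graph over features, as produced by
#' [inferNetwork()] / [buildNetwork()], with the inference provenance
#' (selected penalty, instability at selection, StARS parameters).
#'
#' @slot nodes data.frame(feature_id, domain_class, mean_rel_abundance).
#' @slot edges data.frame(from, to, weight, sign, stability); each unordered
#'   pair stored once with `from < to` in node order; `sign` is `"+"`/`"-"`
#'   and always matches `sign(weight)`; weights are non-zero.
#' @slot lambdaSelected selected regularization penalty.
#' @slot instability total edge instability at the selected penalty.
#' @slot params list of inference parameters (n_subsamples, subsample_size,
#'   lambda_path, beta_threshold, rule, pseudocount, sign_conflicts).
#' @export
setClass("AssociationNetwork",
  representation(nodes = "data.frame", edges = "data.frame",
                 lambdaSelected = "numeric", instability = "numeric",
                 params = "list"))

setValidity("AssociationNetwork", function(object) {
  msg <- character()
  e <- object@edges
  need <- c("from", "to", "weight", "sign")
  if (!all(need %in% names(e))) msg <- c(msg, "edges needs from, to, weight, sign")
  else if (nrow(e)) {
    idx_from <- match(e$from, object@nodes$feature_id)
    idx_to <- match(e$to, object@nodes$feature_id)
    if (anyNA(idx_from) || anyNA(idx_to)) msg <- c(msg, "edge endpoint not in nodes")
    else if (any(idx_from >= idx_to)) msg <- c(msg, "edges must be stored once with from < to")
    if (any(e$weight == 0)) msg <- c(msg, "edge weights must be non-zero")
    if (!all(e$sign == ifelse(e$weight > 0, "+", "-")))
      msg <- c(msg, "sign must match sign(weight)")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "AssociationNetwork", function(object) {
  e <- object@edges
  cat("AssociationNetwork:", nrow(object@nodes), "nodes,", nrow(e), "edges (",
      sum(e$sign == "+"), "positive /", sum(e$sign == "-"), "negative )\n")
  if (length(object@lambdaSelected))
    cat("  lambda =", signif(object@lambdaSelected, 4),
        " instability =", signif(object@instability, 4), "\n")
  invisible(object)
})

#' Module partition of a network
#'
#' Node-to-module assignment maximizing Newman-Girvan modularity on the
#' unweighted graph, with the achieved modularity Q.
#'
#' @slot membership named integer vector, node -> module id (1-based).
#' @slot Q achieved modularity, in \[-0.5, 1\].
#' @slot method label of the optimizer used.
#' @slot seed RNG seed used for the restarts.
#' @export
setClass("ModulePartition",
  representation(membership = "integer", Q = "numeric",
                 method = "character", seed = "integer"))

setValidity("ModulePartition", function(object) {
  msg <- character()
  if (is.null(names(object@membership))) msg <- c(msg, "membership must be named")
  if (anyNA(object@membership)) msg <- c(msg, "every node must be assigned a module")
  if (object@Q < -0.5 - 1e-12 || object@Q > 1 + 1e-12)
    msg <- c(msg, "Q out of [-0.5, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ModulePartition", function(object) {
  cat("ModulePartition:", length(unique(object@membership)), "modules over",
      length(object@membership), "nodes, Q =", signif(object@Q, 4),
      paste0("(", object@method, ")"), "\n")
  invisible(object)
})

#' Accessors for network containers
#'
#' @param x an `AssociationNetwork`, `GroundTruthGraph` or `ModulePartition`.
#' @return `networkEdges`: the edge data.frame; `networkNodes`: the node
#'   data.frame; `moduleMembership`: named integer vector.
#' @export
networkEdges <- function(x) {
  if (methods::is(x, "GroundTruthGraph")) return(x@edges)
  x@edges
}

#' @rdname networkEdges
#' @export
networkNodes <- function(x) x@nodes

#' @rdname networkEdges
#' @export
moduleMembership <- function(x) x@membership
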