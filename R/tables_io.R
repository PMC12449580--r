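#' Read an ASV count table
#'
#' Reads a count table from tab-separated text or BIOM v1 JSON into a
#' [BiofilmExperiment-class]. The TSV dialect has features as rows and
#' samples as columns, with `#ASV_ID` in the first header cell; BIOM input
#' is parsed with the Bioconductor **biomformat** package. Samples whose
#' total is zero are dropped with a warning (a validated table always has
#' positive sample totals).
#'
#' @param path path to the file.
#' @param format `"tsv"` or `"biom_json"`.
#' @return A [BiofilmExperiment-class] (no sample metadata / taxonomy
#'   attached; see [readSampleMetadata()] and [readTaxonomy()]).
#' @seealso [writeCountTable()]
#' @export
readCountTable <- function(path, format = c("tsv", "biom_json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  m <- switch(format,
    tsv = {
      df <- utils::read.delim(path, check.names = FALSE, comment.char = "")
      first <- names(df)[1]
      if (!identical(first, "#ASV_ID") && !identical(first, "X.ASV_ID"))
        stop("TSV count table must have '#ASV_ID' as first header cell")
      ids <- as.character(df[[1]])
      mm <- as.matrix(df[, -1, drop = FALSE])
      rownames(mm) <- ids
      mm
    },
    biom_json = {
      b <- biomformat::read_biom(path)
      as(biomformat::biom_data(b), "matrix")
    })
  if (anyDuplicated(rownames(m))) stop("duplicate feature IDs in ", path)
  if (anyDuplicated(colnames(m))) stop("duplicate sample IDs in ", path)
  if (!is.numeric(m) || any(!is.finite(m))) stop("non-numeric entries in ", path)
  if (any(m < 0)) stop("negative counts in ", path)
  if (any(m != round(m))) stop("non-integer counts in ", path)
  zero <- colSums(m) == 0
  if (any(zero)) {
    warning("dropping ", sum(zero), " zero-total sample(s): ",
            paste(colnames(m)[zero], collapse = ", "))
    m <- m[, !zero, drop = FALSE]
  }
  if (ncol(m) == 0) stop("no samples with positive total in ", path)
  BiofilmExperiment(m)
}

#' Write a count table
#'
#' Inverse of [readCountTable()]: TSV with features as rows (`#ASV_ID`
#' header) or BIOM v1 JSON via **biomformat**. Round-trips preserve the
#' matrix, IDs and their order.
#'
#' @param x a `BiofilmExperiment` or features x samples matrix.
#' @param path output path.
#' @param format `"tsv"` or `"biom_json"`.
#' @return `path`, invisibly.
#' @export
writeCountTable <- function(x, path, format = c("tsv", "biom_json")) {
  format <- match.arg(format)
  m <- if (methods::is(x, "BiofilmExperiment")) counts(x) else as.matrix(x)
  if (format == "tsv") {
    df <- data.frame("#ASV_ID" = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    biomformat::write_biom(biomformat::make_biom(m), path)
  }
  invisible(path)
}

#' Read sample metadata / feature taxonomy
#'
#' `readSampleMetadata` reads a TSV with columns `sample_id`, `treatment`,
#' `substrate`, `timepoint`, `panel`, `bottle`. `readTaxonomy` reads a TSV
#' with columns `feature_id`, `domain_class`, `lineage`, `copy_number`
#' (copy number may be empty for microalgae). Both validate uniqueness of
#' the IDs and the categorical levels.
#'
#' @param path path to the TSV.
#' @return a `data.frame` keyed by its first column.
#' @export
readSampleMetadata <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  need <- c("sample_id", "treatment", "substrate", "timepoint")
  if (!all(need %in% names(df)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in metadata")
  for (col in intersect(c(need, "panel", "bottle"), names(df))) {
    if (any(is.na(df[[col]]) | df[[col]] == ""))
      stop("empty values in metadata column ", col)
    df[[col]] <- as.character(df[[col]])
  }
  df
}

#' @rdname readSampleMetadata
#' @export
readTaxonomy <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  need <- c("feature_id", "domain_class")
  if (!all(need %in% names(df)))
    stop("taxonomy must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$feature_id)) stop("duplicate feature_id in taxonomy")
  bad <- !df$domain_class %in% c("prokaryote", "microalga")
  if (any(bad)) stop("domain_class must be 'prokaryote' or 'microalga'")
  if ("copy_number" %in% names(df)) {
    cn <- df$copy_number
    if (any(!is.na(cn) & cn <= 0)) stop("copy_number must be > 0 where present")
  }
  df
}

#' Attach metadata and taxonomy to a count table
#'
#' @param x a `BiofilmExperiment`.
#' @param sampleData data.frame from [readSampleMetadata()].
#' @param taxonomy data.frame from [readTaxonomy()].
#' @return `x` with `colData` / `rowData` populated; samples/features without
#'   a matching annotation row raise an error.
#' @export
attachAnnotation <- function(x, sampleData = NULL, taxonomy = NULL) {
  if (!is.null(sampleData))
    SummarizedExperiment::colData(x) <-
      .align_annotation(sampleData, colnames(x), "sample_id")
  if (!is.null(taxonomy))
    SummarizedExperiment::rowData(x) <-
      .align_annotation(taxonomy, rownames(x), "feature_id")
  methods::validObject(x)
  x
}

#' Remove shallow samples
#'
#' Retains exactly the samples whose read total is at least `min_reads`
#' (inclusive boundary: a sample with exactly `min_reads` reads is kept,
#' matching "samples with fewer than `min_reads` reads removed"). Typical
#' thresholds are 2000 reads for prokaryote tables and 100 for microalgae.
#'
#' @param x a `BiofilmExperiment`.
#' @param min_reads positive integer threshold.
#' @return the filtered `BiofilmExperiment`.
#' @export
filterMinDepth <- function(x, min_reads) {
  stopifnot(min_reads >= 1)
  keep <- sampleTotals(x) >= min_reads
  if (!any(keep)) stop("filterMinDepth: all samples removed at min_reads = ", min_reads)
  x[, keep]
}

#' 16S gene-copy-number correction
#'
#' Divides each feature's counts by its 16S rRNA gene copy number, taken
#' from the taxonomy annotation (`copy_number` column of `rowData`) or from
#' a supplied taxonomy table. Features without a copy number (microalgae,
#' or prokaryotes missing from the reference) are divided by 1 and reported
#' in a message — reference copy-number databases never cover all taxa.
#' Zeros are preserved exactly; the result is real-valued.
#'
#' @param x a `BiofilmExperiment`.
#' @param taxonomy optional data.frame with `feature_id` and `copy_number`;
#'   defaults to `rowData(x)`.
#' @return a `BiofilmExperiment` whose `counts` assay holds the corrected
#'   real-valued abundances.
#' @export
copyNumberNormalize <- function(x, taxonomy = NULL) {
  if (is.null(taxonomy)) {
    rd <- SummarizedExperiment::rowData(x)
    if (!"copy_number" %in% names(rd))
      stop("no copy_number in rowData and no taxonomy supplied")
    cn <- rd$copy_number
    names(cn) <- rownames(x)
  } else {
    cn <- taxonomy$copy_number[match(rownames(x), taxonomy$feature_id)]
    names(cn) <- rownames(x)
  }
  if (any(!is.na(cn) & cn <= 0)) stop("copy_number must be > 0 where present")
  miss <- is.na(cn)
  if (any(miss))
    message("copyNumberNormalize: ", sum(miss),
            " feature(s) without copy number treated as 1")
  cn[miss] <- 1
  m <- counts(x) / cn          # recycles along rows (features)
  se <- x
  SummarizedExperiment::assays(se)$counts <- m
  se
}
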