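#' Construct a cells x features UMI count matrix
#'
#' The central container of the pipeline: a sparse non-negative integer
#' matrix with cells as rows and features (genes and/or TE loci) as
#' columns, a per-feature kind flag, and optional per-cell cluster and
#' sample labels.
#'
#' @param counts cells x features matrix of non-negative integers (dense or
#'   sparse); must carry unique row (cell barcode) and column (feature id)
#'   names.
#' @param feature_kind character vector, one of `"gene"` or `"te_locus"`
#'   per feature. A single value is recycled. Default all `"gene"`.
#' @param cluster_labels optional per-cell cluster assignment.
#' @param sample_labels optional per-cell sample-of-origin label.
#' @return An object of class `CountMatrix`.
#' @export
count_matrix <- function(counts, feature_kind = "gene",
                         cluster_labels = NULL, sample_labels = NULL) {
  counts <- as(as(counts, "CsparseMatrix"), "generalMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    integrity_error("counts must have cell (row) and feature (column) names")
  if (length(feature_kind) == 1L)
    feature_kind <- rep(feature_kind, ncol(counts))
  m <- structure(
    list(counts = counts,
         feature_kind = as.character(feature_kind),
         cluster_labels = if (!is.null(cluster_labels)) as.character(cluster_labels),
         sample_labels = if (!is.null(sample_labels)) as.character(sample_labels)),
    class = "CountMatrix")
  validate_count_matrix(m)
  m
}

#' Validate CountMatrix invariants
#'
#' Checks non-negativity, integrality, unique cell/feature identifiers,
#' legal kind flags and label lengths. Called by all constructors; exported
#' so readers of external data can re-assert the contract.
#'
#' @param m a `CountMatrix`.
#' @return `m`, invisibly, if valid; otherwise an integrity error.
#' @export
validate_count_matrix <- function(m) {
  x <- m$counts
  if (anyDuplicated(rownames(x)))
    integrity_error("duplicate cell barcodes")
  if (anyDuplicated(colnames(x)))
    integrity_error("duplicate feature ids")
  if (length(x@x) && (any(x@x < 0) || any(x@x != round(x@x))))
    integrity_error("counts must be non-negative integers")
  if (length(m$feature_kind) != ncol(x))
    integrity_error("feature_kind length must equal number of features")
  if (!all(m$feature_kind %in% c("gene", "te_locus")))
    integrity_error("feature_kind values must be 'gene' or 'te_locus'")
  for (lab in c("cluster_labels", "sample_labels"))
    if (!is.null(m[[lab]]) && length(m[[lab]]) != nrow(x))
      integrity_error(sprintf("%s length must equal number of cells", lab))
  invisible(m)
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d cells x %d features (%d genes, %d TE loci)\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$feature_kind == "gene"),
              sum(x$feature_kind == "te_locus")))
  if (!is.null(x$cluster_labels)) {
    tb <- table(x$cluster_labels)
    cat("clusters:", paste(sprintf("%s (%d)", names(tb), tb), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of cells / features in a count or normalized matrix
#' @param m a `CountMatrix` or `NormalizedMatrix`.
#' @return integer count.
#' @export
n_cells <- function(m) nrow(if (!is.null(m$counts)) m$counts else m$values)

#' @rdname n_cells
#' @export
n_features <- function(m) ncol(if (!is.null(m$counts)) m$counts else m$values)

#' Cell barcodes / feature identifiers
#' @param m a `CountMatrix` or `NormalizedMatrix`.
#' @return character vector.
#' @export
cell_ids <- function(m) rownames(if (!is.null(m$counts)) m$counts else m$values)

#' @rdname cell_ids
#' @export
feature_ids <- function(m) colnames(if (!is.null(m$counts)) m$counts else m$values)

# internal row/column subsetting that keeps labels aligned
subset_cells <- function(m, idx) {
  m$counts <- m$counts[idx, , drop = FALSE]
  if (!is.null(m$cluster_labels)) m$cluster_labels <- m$cluster_labels[idx]
  if (!is.null(m$sample_labels)) m$sample_labels <- m$sample_labels[idx]
  m
}

subset_features <- function(m, idx) {
  m$counts <- m$counts[, idx, drop = FALSE]
  m$feature_kind <- m$feature_kind[idx]
  m
}

#' Construct a genomic feature annotation table
#'
#' Records for genes and TE loci in 0-based half-open coordinates. TE loci
#' carry the RepeatMasker hierarchy (subfamily, family, class); gene records
#' leave those fields `NA`.
#'
#' @param df data frame with columns `feature_id`, `chrom`, `start`, `end`,
#'   `strand` (`+`, `-` or `.`), `kind` (`gene` or `te_locus`), and
#'   `subfamily`, `family`, `te_class` (NA for genes).
#' @return A `FeatureAnnotation` (a validated data frame).
#' @export
feature_annotation <- function(df) {
  need <- c("feature_id", "chrom", "start", "end", "strand", "kind")
  if (!all(need %in% names(df)))
    integrity_error(paste("annotation must have columns:", paste(need, collapse = ", ")))
  for (h in c("subfamily", "family", "te_class"))
    if (is.null(df[[h]])) df[[h]] <- NA_character_
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  rownames(df) <- NULL
  class(df) <- c("FeatureAnnotation", "data.frame")
  validate_feature_annotation(df)
  df
}

#' Validate FeatureAnnotation invariants
#' @param df a `FeatureAnnotation`.
#' @return `df`, invisibly, if valid.
#' @export
validate_feature_annotation <- function(df) {
  if (anyDuplicated(df$feature_id))
    format_error("duplicate feature_id in annotation")
  if (any(df$start >= df$end))
    format_error("annotation requires start < end (0-based half-open)")
  if (!all(df$strand %in% c("+", "-", ".")))
    format_error("strand must be one of '+', '-', '.'")
  if (!all(df$kind %in% c("gene", "te_locus")))
    format_error("kind must be 'gene' or 'te_locus'")
  te <- df$kind == "te_locus"
  if (any(te) && (anyNA(df$subfamily[te]) || anyNA(df$family[te]) || anyNA(df$te_class[te])))
    format_error("TE locus records require subfamily, family and te_class")
  invisible(df)
}

#' Construct a set of genomic intervals (peaks or TE loci)
#'
#' Strand-agnostic intervals in 0-based half-open coordinates with an
#' optional score, as used for ATAC-seq peaks.
#'
#' @param chrom chromosome names.
#' @param start,end 0-based half-open coordinates, `start < end`.
#' @param score optional numeric score per interval (e.g. peak strength).
#' @return An `IntervalSet` (a validated data frame).
#' @export
interval_set <- function(chrom, start, end, score = NA_real_) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start), end = as.numeric(end),
                   score = as.numeric(score), stringsAsFactors = FALSE)
  if (any(df$start >= df$end))
    format_error("intervals require start < end (0-based half-open)")
  if (any(df$start < 0))
    format_error("negative interval start")
  class(df) <- c("IntervalSet", "data.frame")
  df
}

# an empty, well-typed IntervalSet
empty_interval_set <- function() {
  df <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                   score = numeric(), stringsAsFactors = FALSE)
  class(df) <- c("IntervalSet", "data.frame")
  df
}

#' Construct a genome as a chromosome-size map
#'
#' @param sizes positive lengths in bases, named by chromosome.
#' @return A `Genome`: a named numeric vector with class attribute.
#' @export
genome_sizes <- function(sizes) {
  if (is.null(names(sizes)) || anyDuplicated(names(sizes)))
    integrity_error("genome sizes must be uniquely named by chromosome")
  if (any(sizes <= 0) || any(sizes != round(sizes)))
    integrity_error("chromosome lengths must be positive integers")
  structure(setNames(as.numeric(sizes), names(sizes)), class = "Genome")
}

#' Check intervals against a genome
#'
#' Verifies every interval's chromosome is present and its end does not
#' exceed the chromosome length.
#'
#' @param iv an `IntervalSet` or `FeatureAnnotation`.
#' @param genome a `Genome` from [genome_sizes()] or [read_chrom_sizes()].
#' @return `iv`, invisibly, if consistent; otherwise an integrity error.
#' @export
validate_intervals <- function(iv, genome) {
  missing_chrom <- setdiff(unique(iv$chrom), names(genome))
  if (length(missing_chrom))
    integrity_error(paste("chromosomes absent from genome:",
                          paste(missing_chrom, collapse = ", ")))
  if (any(iv$end > unclass(genome)[iv$chrom]))
    integrity_error("interval end beyond chromosome length")
  invisible(iv)
}
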