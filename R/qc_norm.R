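# Cell/gene quality filters and per-cell log normalization.
# Boundary semantics follow the filtering rules literally: "fewer than
# 1800 genes" removes cells with <= 1799 detected genes; "five or fewer
# cells" removes genes detected in <= 5 cells. Detection means count > 0.

#' Remove cells with too few detected genes
#'
#' A gene is "detected" in a cell when its count is nonzero; only features
#' of kind `gene` contribute, so TE loci in a combined matrix do not rescue
#' low-complexity cells.
#'
#' @param m a `CountMatrix`.
#' @param min_genes minimum detected-gene count a cell must reach to be
#'   retained (default 1800).
#' @return The filtered `CountMatrix`, cell order preserved.
#' @export
filter_cells <- function(m, min_genes = 1800) {
  if (min_genes < 0) config_error("min_genes must be >= 0")
  gene_cols <- which(m$feature_kind == "gene")
  detected <- rowSums(m$counts[, gene_cols, drop = FALSE] > 0)
  subset_cells(m, detected >= min_genes)
}

#' Remove weakly covered genes
#'
#' Retains genes with total count >= `min_total_reads` across all cells AND
#' detected (count > 0) in at least `min_cells_detected` cells. Features of
#' kind `te_locus` are untouched (TE loci have their own detection filter,
#' [filter_te_loci()]).
#'
#' @param m a `CountMatrix`.
#' @param min_total_reads minimum total count per gene (default 10).
#' @param min_cells_detected minimum number of cells with a nonzero count
#'   (default 6, i.e. genes in five or fewer cells are dropped).
#' @return The filtered `CountMatrix`, feature order preserved.
#' @export
filter_genes <- function(m, min_total_reads = 10, min_cells_detected = 6) {
  if (min_total_reads < 0 || min_cells_detected < 0)
    config_error("filter thresholds must be >= 0")
  is_gene <- m$feature_kind == "gene"
  tot <- colSums(m$counts)
  det <- colSums(m$counts > 0)
  keep <- !is_gene | (tot >= min_total_reads & det >= min_cells_detected)
  subset_features(m, keep)
}

#' Per-cell scaled log2 normalization
#'
#' Scales each cell's counts to a common total and log-transforms with a
#' pseudocount of 1:
#' `tpm` gives log2(count / cell_total * 1e6 + 1) (length-free TPM, the
#' natural reading for 3'-UMI counts) and `cp10k` gives
#' log2(count / cell_total * 1e4 + 1). Cell totals are computed over all
#' features present in the matrix unless `cell_totals` supplies externally
#' computed totals (used when normalizing a TE submatrix by the combined
#' gene+TE library size).
#'
#' @param m a `CountMatrix`.
#' @param scheme `"tpm"` or `"cp10k"`.
#' @param cell_totals optional numeric vector of per-cell totals, named by
#'   cell barcode or aligned to the matrix rows.
#' @return A `NormalizedMatrix`: sparse cells x features log2 values with
#'   the scheme, feature kinds, labels and the totals used.
#' @export
normalize_counts <- function(m, scheme = c("tpm", "cp10k"), cell_totals = NULL) {
  scheme <- match.arg(scheme)
  scale_to <- if (scheme == "tpm") 1e6 else 1e4
  if (is.null(cell_totals)) {
    cell_totals <- rowSums(m$counts)
  } else {
    if (!is.null(names(cell_totals))) {
      if (!all(rownames(m$counts) %in% names(cell_totals)))
        integrity_error("cell_totals missing entries for some cells")
      cell_totals <- cell_totals[rownames(m$counts)]
    } else if (length(cell_totals) != nrow(m$counts)) {
      integrity_error("cell_totals length must equal number of cells")
    }
  }
  if (any(cell_totals <= 0))
    integrity_error("cells with zero total counts: filter before normalizing")
  v <- Diagonal(x = scale_to / cell_totals) %*% m$counts
  v <- as(as(v, "CsparseMatrix"), "generalMatrix")
  v@x <- log2(v@x + 1)
  dimnames(v) <- dimnames(m$counts)
  structure(
    list(values = v, scheme = paste0(scheme, "_log2"),
         feature_kind = m$feature_kind,
         cluster_labels = m$cluster_labels,
         sample_labels = m$sample_labels,
         cell_totals = as.numeric(cell_totals)),
    class = "NormalizedMatrix")
}

#' @export
print.NormalizedMatrix <- function(x, ...) {
  cat(sprintf("NormalizedMatrix (%s): %d cells x %d features\n",
              x$scheme, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Percent composition of observed category counts
#'
#' Turns raw category counts (e.g. cells positive for a marker combination
#' in an imaging field) into percentages of their total.
#'
#' @param counts named or unnamed non-negative counts.
#' @param digits decimal places to round to (default 1, the convention for
#'   reported cell-composition percentages).
#' @return Numeric vector of percentages summing to ~100.
#' @export
composition_percent <- function(counts, digits = 1) {
  if (any(counts < 0)) input_error("counts must be non-negative")
  total <- sum(counts)
  if (total == 0) undefined_error("composition of an empty population")
  round(100 * counts / total, digits)
}
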