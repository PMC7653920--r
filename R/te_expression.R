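# Locus-resolution TE quantification: combined gene+TE annotation,
# unique-overlap read assignment, detection filtering, hierarchical
# aggregation (locus -> subfamily -> family -> class -> total), CP10k
# normalization against combined library sizes, and variable-TE ranking.
#
# Order of operations mirrors the analysis convention: loci are first
# filtered by detection, then summed; reads compatible with more than one
# feature of the combined annotation are discarded (deterministic
# unique-assignment rule).

#' Merge gene and TE annotations into one combined annotation
#'
#' If feature ids collide between the two inputs, TE ids are prefixed with
#' `te_prefix`; a collision surviving that is an error.
#'
#' @param genes `FeatureAnnotation` of gene records.
#' @param tes `FeatureAnnotation` of TE locus records.
#' @param te_prefix prefix used to disambiguate colliding TE ids
#'   (default `"TE:"`).
#' @return The union `FeatureAnnotation`.
#' @export
build_combined_annotation <- function(genes, tes, te_prefix = "TE:") {
  if (length(intersect(genes$feature_id, tes$feature_id)))
    tes$feature_id <- paste0(te_prefix, tes$feature_id)
  if (length(intersect(genes$feature_id, tes$feature_id)))
    integrity_error("feature id collision between genes and TE loci persists after prefixing")
  feature_annotation(rbind(as.data.frame(genes), as.data.frame(tes)))
}

#' Count read assignments to annotated features
#'
#' Assigns each read (0-based half-open footprint) to the unique feature it
#' overlaps by at least 1 bp. Reads overlapping no feature, more than one
#' feature, an unknown chromosome, or carrying a barcode outside `cells`
#' are discarded; `assigned + discarded` always equals the number of input
#' reads (see `attr(result, "assignment_stats")`).
#'
#' @param reads data frame with columns `barcode`, `chrom`, `start`, `end`.
#' @param annotation a `FeatureAnnotation` (typically combined gene+TE).
#' @param cells character vector of valid cell barcodes.
#' @return A [count_matrix()] of `length(cells)` x `nrow(annotation)`
#'   counts with an `assignment_stats` attribute.
#' @export
count_assignments <- function(reads, annotation, cells) {
  if (anyDuplicated(cells)) integrity_error("duplicate cell barcodes")
  n_reads <- nrow(reads)
  known_bc <- reads$barcode %in% cells
  known_chrom <- reads$chrom %in% unique(annotation$chrom)
  usable <- which(known_bc & known_chrom)

  hits_per_read <- integer(n_reads)
  feat_of_read <- integer(n_reads)
  if (length(usable)) {
    # +1: internal half-open [start,end) to IRanges 1-based closed
    rgr <- GRanges(reads$chrom[usable],
                   IRanges(reads$start[usable] + 1L, reads$end[usable]))
    fgr <- GRanges(annotation$chrom,
                   IRanges(annotation$start + 1L, annotation$end))
    ov <- findOverlaps(rgr, fgr, ignore.strand = TRUE)
    tab <- tabulate(queryHits(ov), nbins = length(usable))
    hits_per_read[usable] <- tab
    first_hit <- ov[!duplicated(queryHits(ov))]
    feat_of_read[usable[queryHits(first_hit)]] <- subjectHits(first_hit)
  }

  assigned <- which(hits_per_read == 1L)
  counts <- sparseMatrix(
    i = match(reads$barcode[assigned], cells),
    j = feat_of_read[assigned], x = 1,
    dims = c(length(cells), nrow(annotation)),
    dimnames = list(cells, annotation$feature_id))
  m <- count_matrix(counts, feature_kind = annotation$kind)
  attr(m, "assignment_stats") <- list(
    input = n_reads,
    assigned = length(assigned),
    discarded_ambiguous = sum(hits_per_read > 1L),
    discarded_no_overlap = sum(hits_per_read == 0L & known_bc & known_chrom),
    discarded_unknown_chrom = sum(known_bc & !known_chrom),
    discarded_unknown_barcode = sum(!known_bc))
  m
}

#' Filter TE loci by detection fraction
#'
#' Keeps TE loci detected (count > 0) in at least `min_cell_fraction` of
#' cells; the boundary is inclusive (detected in exactly 0.5% of cells is
#' retained under the default). Gene features, if present, pass through.
#'
#' @param m a `CountMatrix` at TE locus resolution.
#' @param min_cell_fraction detection threshold as a fraction of cells
#'   (default 0.005, i.e. 0.5%).
#' @return The filtered matrix.
#' @export
filter_te_loci <- function(m, min_cell_fraction = 0.005) {
  if (min_cell_fraction < 0 || min_cell_fraction > 1)
    config_error("min_cell_fraction must be in [0, 1]")
  frac <- colSums(m$counts > 0) / nrow(m$counts)
  keep <- m$feature_kind != "te_locus" | frac >= min_cell_fraction
  subset_features(m, keep)
}

#' Aggregate TE locus counts up the RepeatMasker hierarchy
#'
#' Sums per-cell counts of all loci belonging to each subfamily, family,
#' class, or into a single total. Groups emptied by upstream locus
#' filtering are absent from the output rather than zero rows. Input must
#' contain only TE locus features (subset a combined matrix first).
#'
#' @param m a `CountMatrix` of TE loci.
#' @param annotation a `FeatureAnnotation` carrying the hierarchy for every
#'   locus in `m`.
#' @param level one of `"subfamily"`, `"family"`, `"class"`, `"total"`.
#' @return A `CountMatrix` whose features are hierarchy names, with an
#'   `aggregation_level` attribute.
#' @export
aggregate_te <- function(m, annotation,
                         level = c("subfamily", "family", "class", "total")) {
  level <- match.arg(level)
  if (any(m$feature_kind != "te_locus"))
    input_error("aggregate_te expects a TE-locus-only matrix")
  loci <- colnames(m$counts)
  row <- match(loci, annotation$feature_id)
  if (anyNA(row))
    integrity_error("loci in matrix missing from annotation")
  group <- switch(level,
                  subfamily = annotation$subfamily[row],
                  family = annotation$family[row],
                  class = annotation$te_class[row],
                  total = rep("TE_total", length(row)))
  if (anyNA(group))
    integrity_error(sprintf("missing %s value for some loci", level))
  groups <- unique(group)
  ind <- sparseMatrix(i = seq_along(group), j = match(group, groups), x = 1,
                      dims = c(length(group), length(groups)))
  agg <- m$counts %*% ind
  agg <- as(as(agg, "CsparseMatrix"), "generalMatrix")
  dimnames(agg) <- list(rownames(m$counts), groups)
  out <- count_matrix(agg, feature_kind = "te_locus",
                      cluster_labels = m$cluster_labels,
                      sample_labels = m$sample_labels)
  attr(out, "aggregation_level") <- level
  out
}

#' Normalize TE counts by combined library sizes
#'
#' log2(CP10k + 1) normalization of a TE matrix using per-cell totals from
#' the full combined gene+TE quantification, so TE abundances are on the
#' same per-cell scale as gene expression rather than summing to 10k over
#' TEs alone.
#'
#' @param m a TE `CountMatrix` (locus level or aggregated).
#' @param cell_totals per-cell totals of the combined matrix, named by
#'   barcode or aligned to rows.
#' @return A `NormalizedMatrix` with scheme `cp10k_log2`.
#' @export
te_normalize <- function(m, cell_totals) {
  normalize_counts(m, scheme = "cp10k", cell_totals = cell_totals)
}

#' Rank TE features by expression variability
#'
#' Ranks features (typically TE subfamilies) by the variance of their
#' normalized log2 values across cells and returns the top `n` in rank
#' order, ties broken lexicographically by feature id for determinism.
#'
#' @param norm a `NormalizedMatrix` over TE features.
#' @param n number of features to return (`0 < n <=` number of features).
#' @return Data frame with `feature_id`, `variance`, `rank`.
#' @export
variable_tes <- function(norm, n) {
  p <- ncol(norm$values)
  if (n <= 0) config_error("n must be positive")
  if (n > p) config_error("n exceeds the number of features")
  x <- norm$values
  nc <- nrow(x)
  mu <- as.numeric(colMeans(x))
  v <- (as.numeric(colSums(x^2)) - nc * mu^2) / (nc - 1)
  v[v < 0] <- 0
  ord <- order(-v, colnames(x))
  data.frame(feature_id = colnames(x)[ord][seq_len(n)],
             variance = v[ord][seq_len(n)],
             rank = seq_len(n), stringsAsFactors = FALSE)
}

#' Per-stage summary of total TE expression
#'
#' Summarizes total TE expression per cell cluster (mean, SD, n) in a
#' supplied developmental stage order, the summary behind "TEs are globally
#' upregulated over time" style statements.
#'
#' @param norm a `NormalizedMatrix` at the `total` aggregation level
#'   (single feature).
#' @param labels per-cell cluster labels; defaults to those stored.
#' @param stage_order optional ordering of cluster names for the output.
#' @return Data frame with `cluster`, `n_cells`, `mean`, `sd`.
#' @export
te_stage_dynamics <- function(norm, labels = NULL, stage_order = NULL) {
  if (is.null(labels)) labels <- norm$cluster_labels
  if (is.null(labels)) input_error("no cluster labels supplied or stored")
  if (ncol(norm$values) != 1)
    input_error("expected a total-level matrix with a single feature")
  x <- as.numeric(norm$values[, 1])
  clusters <- if (is.null(stage_order)) unique(labels) else stage_order
  if (!all(labels %in% clusters))
    input_error("stage_order omits some observed clusters")
  out <- data.frame(
    cluster = clusters,
    n_cells = as.integer(table(factor(labels, levels = clusters))),
    mean = vapply(clusters, function(k) mean(x[labels == k]), 0),
    sd = vapply(clusters, function(k) sd(x[labels == k]), 0),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
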