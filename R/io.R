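# Readers/writers for the standard formats the pipeline touches.
# Internal convention everywhere: 0-based half-open coordinates; only the
# GTF boundary shifts by 1 (GTF is 1-based inclusive). BED needs no shift.

#' Read a 10x-style count-matrix triplet
#'
#' Reads a directory containing `matrix.mtx` (MatrixMarket coordinate
#' format), `features.tsv` and `barcodes.tsv`. The on-disk matrix may be in
#' either orientation (features x cells, the 10x convention, or cells x
#' features); orientation is inferred from the TSV line counts and the
#' returned matrix is always cells x features. The features TSV may carry a
#' third column flagging each feature `gene` or `te_locus`; without it all
#' features are genes.
#'
#' @param dir_path directory holding the triplet.
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(dir_path) {
  paths <- file.path(dir_path, c("matrix.mtx", "features.tsv", "barcodes.tsv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    format_error(paste("missing triplet file(s):", paste(basename(missing), collapse = ", ")))

  mat <- tryCatch(readMM(paths[1]),
                  error = function(e) format_error(paste("bad MatrixMarket file:", conditionMessage(e))))
  feats <- read.table(paths[2], sep = "\t", header = FALSE,
                      colClasses = "character", quote = "")
  bcs <- read.table(paths[3], sep = "\t", header = FALSE,
                    colClasses = "character", quote = "")[[1]]

  n_feat <- nrow(feats); n_bc <- length(bcs)
  if (nrow(mat) == n_feat && ncol(mat) == n_bc) {
    mat <- Matrix::t(mat)               # 10x orientation: features x cells
  } else if (!(nrow(mat) == n_bc && ncol(mat) == n_feat)) {
    integrity_error(sprintf(
      "matrix is %d x %d but features.tsv has %d lines and barcodes.tsv %d",
      nrow(mat), ncol(mat), n_feat, n_bc))
  }
  if (anyDuplicated(bcs)) integrity_error("duplicate cell barcodes in barcodes.tsv")
  if (anyDuplicated(feats[[1]])) integrity_error("duplicate feature ids in features.tsv")

  mat <- as(as(mat, "CsparseMatrix"), "generalMatrix")
  if (length(mat@x) && (any(mat@x < 0) || any(mat@x != round(mat@x))))
    integrity_error("matrix entries must be non-negative integers")
  dimnames(mat) <- list(bcs, feats[[1]])

  kind <- if (ncol(feats) >= 3) feats[[3]] else rep("gene", n_feat)
  kind[kind %in% c("Gene Expression", "")] <- "gene"
  count_matrix(mat, feature_kind = kind)
}

#' Write a count matrix as a 10x-style triplet
#'
#' Emits `matrix.mtx` in the features x cells orientation 10x tools use,
#' plus `features.tsv` (id, id, kind) and `barcodes.tsv`.
#'
#' @param m a `CountMatrix`.
#' @param dir_path output directory (created if absent).
#' @return `dir_path`, invisibly.
#' @export
write_count_matrix <- function(m, dir_path) {
  dir.create(dir_path, showWarnings = FALSE, recursive = TRUE)
  writeMM(Matrix::t(m$counts), file.path(dir_path, "matrix.mtx"))
  feats <- data.frame(id = colnames(m$counts), name = colnames(m$counts),
                      kind = m$feature_kind)
  write.table(feats, file.path(dir_path, "features.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(rownames(m$counts), file.path(dir_path, "barcodes.tsv"))
  invisible(dir_path)
}

#' Read a combined gene/TE annotation from GTF
#'
#' Parses a GTF whose records carry a `gene_id` attribute and, for TE loci,
#' `subfamily`, `family` and `class` attributes (the RepeatMasker
#' hierarchy). A record is a TE locus if its feature-type column is
#' `te_locus` or if it carries a `subfamily` attribute; otherwise a gene.
#' GTF 1-based inclusive coordinates are converted to the package's
#' 0-based half-open convention.
#'
#' @param path GTF file path.
#' @return A [feature_annotation()].
#' @export
read_gtf <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                 error = function(e) format_error(paste("bad GTF:", conditionMessage(e))))
  mc <- as.data.frame(S4Vectors::mcols(gr))
  if (is.null(mc$gene_id) || anyNA(mc$gene_id))
    format_error("every GTF record needs a gene_id attribute")
  for (h in c("subfamily", "family", "class"))
    if (is.null(mc[[h]])) mc[[h]] <- NA_character_
  kind <- ifelse(as.character(mc$type) == "te_locus" | !is.na(mc$subfamily),
                 "te_locus", "gene")
  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "*"] <- "."
  df <- data.frame(feature_id = mc$gene_id,
                   chrom = as.character(GenomeInfoDb::seqnames(gr)),
                   start = BiocGenerics::start(gr) - 1L,   # 1-based -> 0-based
                   end = BiocGenerics::end(gr),
                   strand = strand, kind = kind,
                   subfamily = mc$subfamily, family = mc$family,
                   te_class = mc$class, stringsAsFactors = FALSE)
  if (anyDuplicated(df$feature_id))
    format_error("duplicate feature_id in GTF (one record per feature expected)")
  if (any(df$start >= df$end))
    format_error("GTF record with end <= start after coordinate conversion")
  te <- df$kind == "te_locus"
  if (any(te) && (anyNA(df$subfamily[te]) || anyNA(df$family[te]) || anyNA(df$te_class[te])))
    format_error("TE locus GTF record lacking subfamily/family/class attributes")
  feature_annotation(df)
}

#' Write a FeatureAnnotation as GTF
#'
#' One line per feature; type column is the feature kind; TE hierarchy is
#' emitted as `subfamily`/`family`/`class` attributes. Coordinates are
#' shifted back to GTF's 1-based inclusive convention.
#'
#' @param ann a `FeatureAnnotation`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(ann, path) {
  attr_str <- sprintf("gene_id \"%s\";", ann$feature_id)
  te <- ann$kind == "te_locus"
  attr_str[te] <- sprintf(
    "%s subfamily \"%s\"; family \"%s\"; class \"%s\";",
    attr_str[te], ann$subfamily[te], ann$family[te], ann$te_class[te])
  lines <- sprintf("%s\tscTEtools\t%s\t%d\t%d\t.\t%s\t.\t%s",
                   ann$chrom, ann$kind, ann$start + 1L, ann$end,
                   ann$strand, attr_str)
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED3/BED5 peak file
#'
#' BED is already 0-based half-open, so coordinates pass through unshifted.
#' A fifth column, when present, is kept as the interval score.
#'
#' @param path BED file path.
#' @return An [interval_set()], rows in file order.
#' @export
read_bed <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "bed"),
                 error = function(e) format_error(paste("bad BED:", conditionMessage(e))))
  score <- S4Vectors::mcols(gr)$score
  if (is.null(score)) score <- NA_real_
  iv <- tryCatch(
    interval_set(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                 start = BiocGenerics::start(gr) - 1L, # undo import's 1-based shift
                 end = BiocGenerics::end(gr), score = score),
    scte_format_error = function(e) format_error(paste("bad BED:", conditionMessage(e))))
  iv
}

#' Write an IntervalSet as BED
#'
#' Emits BED3 when no interval has a score, else BED5 with `.` names.
#'
#' @param iv an `IntervalSet`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(iv, path) {
  if (all(is.na(iv$score))) {
    lines <- sprintf("%s\t%d\t%d", iv$chrom, as.integer(iv$start), as.integer(iv$end))
  } else {
    lines <- sprintf("%s\t%d\t%d\t.\t%g", iv$chrom, as.integer(iv$start),
                     as.integer(iv$end), iv$score)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a two-column chromosome-sizes file
#'
#' @param path TSV with chromosome name and length columns.
#' @return A [genome_sizes()] map.
#' @export
read_chrom_sizes <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "length"),
                   colClasses = c("character", "numeric"))
  genome_sizes(setNames(df$length, df$chrom))
}

#' Write a table as TSV with a header row
#'
#' The common output format of all pipeline stages.
#'
#' @param table a data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
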