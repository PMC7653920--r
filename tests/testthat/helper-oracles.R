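# Independent oracles and small fixture builders used across the suite.

# all-pairs overlap count: the brute-force oracle for count_overlaps()
brute_force_overlap_count <- function(peaks, loci) {
  hits <- 0L
  for (i in seq_len(nrow(peaks))) {
    for (j in seq_len(nrow(loci))) {
      if (peaks$chrom[i] == loci$chrom[j] &&
          peaks$start[i] < loci$end[j] && loci$start[j] < peaks$end[i]) {
        hits <- hits + 1L
        break
      }
    }
  }
  hits
}

# direct step-up BH: q_(i) = min_{j >= i} p_(j) * m / j, capped at 1
bh_direct <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  out <- numeric(m)
  out[o] <- q
  out
}

# craft a NormalizedMatrix directly from a dense cells x features matrix
make_norm <- function(values, labels = NULL, scheme = "tpm_log2") {
  v <- as(as(Matrix::Matrix(values, sparse = TRUE), "CsparseMatrix"),
          "generalMatrix")
  if (is.null(rownames(v))) rownames(v) <- sprintf("c%03d", seq_len(nrow(v)))
  if (is.null(colnames(v))) colnames(v) <- sprintf("f%03d", seq_len(ncol(v)))
  structure(list(values = v, scheme = scheme,
                 feature_kind = rep("gene", ncol(v)),
                 cluster_labels = labels, sample_labels = NULL,
                 cell_totals = rep(1, nrow(v))),
            class = "NormalizedMatrix")
}

# craft a ClusterProfile from a clusters x features means matrix
make_profile <- function(means) {
  structure(list(means = means,
                 n_cells = stats::setNames(rep(10L, nrow(means)), rownames(means))),
            class = "ClusterProfile")
}

# small count matrix from a dense integer matrix
make_counts <- function(counts, kind = "gene", labels = NULL) {
  if (is.null(rownames(counts))) rownames(counts) <- sprintf("c%03d", seq_len(nrow(counts)))
  if (is.null(colnames(counts))) colnames(counts) <- sprintf("f%03d", seq_len(ncol(counts)))
  count_matrix(counts, feature_kind = kind, cluster_labels = labels)
}

# uniformly random interval sets for property tests
random_intervals <- function(n, chroms, chrom_len, max_len = 500) {
  chrom <- sample(chroms, n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  start <- floor(runif(n) * (chrom_len - len))
  interval_set(chrom, start, start + len)
}
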