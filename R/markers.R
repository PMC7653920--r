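# Differential expression and marker selection on normalized log2 values.
#
# The pairwise DEG rule is multi-criteria: a feature is differential for a
# group when its mean log2 expression in that group exceeds the abundance
# floor, the difference of group means reaches the log2 fold threshold, and
# the BH-adjusted Welch p-value clears the FDR cutoff. Fold change is the
# difference of mean log2(TPM+1) values (delta >= 2 is "fourfold").
# Zero-variance features are assigned p = 1 (kept in the BH family, never
# called), so the multiple-testing burden m is stable.

#' Welch's two-sample t-test (unequal variances)
#'
#' Closed-form Welch statistic with Satterthwaite degrees of freedom and a
#' two-sided p-value. The same kernel is applied column-wise across
#' thousands of features by [pairwise_deg()] and [multigroup_markers()].
#'
#' @param x,y numeric samples with at least 2 observations each.
#' @return List with elements `t`, `df`, `p`.
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    input_error("welch_t needs >= 2 observations per sample")
  s <- welch_stats(list(n = length(x), mean = mean(x), var = var(x)),
                   list(n = length(y), mean = mean(y), var = var(y)))
  if (is.na(s$df) && s$t == 0 && s$p == 1)
    undefined_error("both samples have zero variance: Welch statistic undefined")
  s
}

# vectorized Welch kernel on precomputed group summaries
welch_stats <- function(a, b) {
  se2 <- a$var / a$n + b$var / b$n
  t <- (a$mean - b$mean) / sqrt(se2)
  df <- se2^2 / ((a$var / a$n)^2 / (a$n - 1) + (b$var / b$n)^2 / (b$n - 1))
  p <- 2 * pt(-abs(t), df)
  # zero variance in both groups: no sampling noise to test against;
  # report t = 0, p = 1 so the feature stays in the BH family
  degenerate <- se2 == 0
  t[degenerate] <- 0
  df[degenerate] <- NA_real_
  p[degenerate] <- 1
  list(t = t, df = df, p = p)
}

# per-group column summaries of a cells x features matrix
group_summary <- function(values, idx) {
  x <- values[idx, , drop = FALSE]
  n <- nrow(x)
  mu <- as.numeric(colMeans(x))
  v <- (as.numeric(colSums(x^2)) - n * mu^2) / (n - 1)
  v[v < 0] <- 0                      # guard against catastrophic cancellation
  list(n = n, mean = mu, var = v)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p finite p-values in \[0, 1\].
#' @return Vector of BH-adjusted q-values in input order.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(!is.finite(p)) || any(p < 0) || any(p > 1))
    input_error("p-values must be finite and within [0, 1]")
  p.adjust(p, method = "BH")
}

# map a group specification (cluster name(s), cell ids, logical or integer
# index) onto row indices of a NormalizedMatrix
resolve_group <- function(norm, group) {
  cells <- rownames(norm$values)
  if (is.logical(group)) return(which(group))
  if (is.numeric(group)) return(as.integer(group))
  if (!is.null(norm$cluster_labels) && all(group %in% norm$cluster_labels))
    return(which(norm$cluster_labels %in% group))
  if (all(group %in% cells)) return(match(group, cells))
  input_error("group does not match cluster labels or cell barcodes")
}

#' Pairwise differential expression between two cell groups
#'
#' Applies the multi-criteria DEG rule between groups `a` and `b` of a
#' normalized matrix: Welch's t-test per feature, BH correction across all
#' tested features, then abundance (`mean > min_mean` in the upregulated
#' group), fold (`|delta_log2| >= log2(fold)`) and significance
#' (`fdr < fdr_threshold`) criteria. Defaults are the rule used for
#' pairwise cell-type comparisons: abundance floor 2 on log2(TPM+1),
#' fourfold change, FDR < 0.01.
#'
#' @param norm a `NormalizedMatrix`.
#' @param group_a,group_b cluster name(s), cell barcodes, or row indices.
#' @param min_mean abundance floor on the upregulated group's mean log2
#'   expression (strict `>`; default 2).
#' @param fold linear fold-change threshold (non-strict on the log2 scale:
#'   `|delta| >= log2(fold)`; default 4).
#' @param fdr_threshold FDR significance cutoff (strict `<`; default 0.01).
#' @return A `DEGResult` data frame with one row per feature: group means,
#'   `delta_log2`, Welch `t_stat`/`df`/`p_value`, `fdr`, the three pass
#'   flags and a `deg` call in `{"a", "b", "none"}`.
#' @export
pairwise_deg <- function(norm, group_a, group_b, min_mean = 2.0, fold = 4.0,
                         fdr_threshold = 0.01) {
  ia <- resolve_group(norm, group_a)
  ib <- resolve_group(norm, group_b)
  if (length(ia) < 2 || length(ib) < 2)
    input_error("each group needs at least 2 cells")
  if (fold < 1) config_error("fold threshold must be >= 1")

  a <- group_summary(norm$values, ia)
  b <- group_summary(norm$values, ib)
  w <- welch_stats(a, b)
  fdr <- bh_adjust(w$p)
  delta <- a$mean - b$mean

  pass_fold <- abs(delta) >= log2(fold)
  pass_abundance <- ifelse(delta >= 0, a$mean > min_mean, b$mean > min_mean)
  pass_fdr <- fdr < fdr_threshold
  deg <- rep("none", length(delta))
  hit <- pass_fold & pass_abundance & pass_fdr
  deg[hit & delta > 0] <- "a"
  deg[hit & delta < 0] <- "b"

  res <- data.frame(feature_id = colnames(norm$values),
                    mean_a = a$mean, mean_b = b$mean, delta_log2 = delta,
                    t_stat = w$t, df = w$df, p_value = w$p, fdr = fdr,
                    pass_abundance = pass_abundance, pass_fold = pass_fold,
                    pass_fdr = pass_fdr, deg = deg,
                    stringsAsFactors = FALSE)
  attr(res, "groups") <- list(a = group_a, b = group_b)
  attr(res, "thresholds") <- c(min_mean = min_mean, fold = fold,
                               fdr = fdr_threshold)
  class(res) <- c("DEGResult", "data.frame")
  res
}

#' One-vs-rest marker genes per cluster
#'
#' For each cluster, tests every feature against all remaining cells
#' (Welch's t, BH across features within the comparison) and calls a marker
#' when `fdr < fdr_threshold` and the cluster mean exceeds the rest mean by
#' more than `log2(fold)` (strict, the ">2-fold higher" rule). A feature
#' may mark at most one cluster: the one maximizing its mean expression.
#'
#' @param norm a `NormalizedMatrix`.
#' @param labels per-cell cluster labels; defaults to those stored in
#'   `norm`.
#' @param fold linear fold threshold (strict on the log2 scale; default 2).
#' @param fdr_threshold FDR cutoff (default 0.05).
#' @return Data frame with columns `feature_id`, `cluster`, `mean_in`,
#'   `mean_rest`, `delta_log2`, `p_value`, `fdr`.
#' @export
multigroup_markers <- function(norm, labels = NULL, fold = 2.0,
                               fdr_threshold = 0.05) {
  if (is.null(labels)) labels <- norm$cluster_labels
  if (is.null(labels)) input_error("no cluster labels supplied or stored")
  if (length(labels) != nrow(norm$values))
    input_error("labels length must equal number of cells")
  clusters <- unique(labels)
  if (length(clusters) < 2) input_error("need at least 2 clusters")
  if (any(table(labels) < 2)) input_error("each cluster needs >= 2 cells")

  feats <- colnames(norm$values)
  cluster_mean <- matrix(NA_real_, length(clusters), length(feats),
                         dimnames = list(clusters, feats))
  rows <- vector("list", length(clusters))
  for (k in seq_along(clusters)) {
    idx <- which(labels == clusters[k])
    a <- group_summary(norm$values, idx)
    b <- group_summary(norm$values, -idx)
    w <- welch_stats(a, b)
    fdr <- bh_adjust(w$p)
    cluster_mean[k, ] <- a$mean
    keep <- fdr < fdr_threshold & (a$mean - b$mean) > log2(fold)
    rows[[k]] <- data.frame(feature_id = feats[keep],
                            cluster = rep(clusters[k], sum(keep)),
                            mean_in = a$mean[keep], mean_rest = b$mean[keep],
                            delta_log2 = (a$mean - b$mean)[keep],
                            p_value = w$p[keep], fdr = fdr[keep],
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (nrow(out)) {
    # a feature marks only the cluster where it is most highly expressed
    best <- clusters[apply(cluster_mean[, out$feature_id, drop = FALSE], 2,
                           which.max)]
    out <- out[out$cluster == best, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Per-cluster mean expression profile
#'
#' Averages normalized log2 values within each cluster, the "averaged
#' expression values for each cell type" used for hierarchical clustering,
#' scatter comparisons and panel selection.
#'
#' @param norm a `NormalizedMatrix`.
#' @param labels per-cell cluster labels; defaults to those stored.
#' @return A `ClusterProfile`: list with `means` (clusters x features
#'   matrix) and `n_cells`.
#' @export
cluster_profile <- function(norm, labels = NULL) {
  if (is.null(labels)) labels <- norm$cluster_labels
  if (is.null(labels)) input_error("no cluster labels supplied or stored")
  if (length(labels) != nrow(norm$values))
    input_error("labels length must equal number of cells")
  clusters <- unique(labels)
  ind <- sparseMatrix(i = seq_along(labels),
                      j = match(labels, clusters),
                      x = 1, dims = c(length(labels), length(clusters)))
  n_c <- as.numeric(table(factor(labels, levels = clusters)))
  means <- as.matrix(Matrix::t(ind) %*% norm$values) / n_c
  dimnames(means) <- list(clusters, colnames(norm$values))
  structure(list(means = means, n_cells = setNames(n_c, clusters)),
            class = "ClusterProfile")
}

#' @export
print.ClusterProfile <- function(x, ...) {
  cat(sprintf("ClusterProfile: %d clusters x %d features\n",
              nrow(x$means), ncol(x$means)))
  invisible(x)
}

#' Squared Pearson correlation of two expression profiles
#'
#' @param a,b numeric profile vectors (e.g. rows of `ClusterProfile$means`).
#'   If both are named, they are matched on shared names first.
#' @return r^2 over the shared features.
#' @export
profile_r2 <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    shared <- intersect(names(a), names(b))
    if (!length(shared)) input_error("profiles share no features")
    a <- a[shared]; b <- b[shared]
  }
  if (length(a) != length(b)) input_error("profiles must have equal length")
  if (var(a) == 0 || var(b) == 0)
    undefined_error("zero-variance profile: correlation undefined")
  cor(a, b)^2
}

#' Restrict a gene panel to genes expressed somewhere
#'
#' Keeps genes whose maximum cluster-mean log2 expression strictly exceeds
#' `min_mean` in at least one cluster (the rule that reduced a curated
#' infertility panel of 105 genes to the 45 expressed ones).
#'
#' @param profile a `ClusterProfile`.
#' @param gene_list candidate gene ids.
#' @param min_mean expression floor (strict `>`; default 1).
#' @return The expressed subset of `gene_list`, order preserved.
#' @export
select_expressed_panel <- function(profile, gene_list, min_mean = 1.0) {
  if (!length(gene_list)) input_error("gene_list is empty")
  present <- gene_list[gene_list %in% colnames(profile$means)]
  if (!length(present)) return(character())
  mx <- apply(profile$means[, present, drop = FALSE], 2, max)
  present[mx > min_mean]
}

# accept either a ClusterProfile + cluster name or a named numeric vector
profile_vector <- function(profile, cluster = NULL) {
  if (is.numeric(profile)) {
    if (is.null(names(profile))) input_error("profile vector must be named")
    return(profile)
  }
  if (is.null(cluster)) input_error("cluster name required with a ClusterProfile")
  if (!cluster %in% rownames(profile$means))
    input_error(sprintf("cluster '%s' absent from profile", cluster))
  profile$means[cluster, ]
}

#' Markers also upregulated in a matched cluster of a second dataset
#'
#' Given a marker set from one dataset, keeps markers whose mean in the
#' target cluster of a second dataset's profile exceeds every other cluster
#' mean there by more than `log2(fold)` (strict). Markers absent from the
#' second dataset's annotation are excluded before testing. This is the
#' selection that reduced 1177 shared T1LC markers to the 316 genes also
#' upregulated in oogonia-like cells.
#'
#' @param markers character marker set.
#' @param other_profile `ClusterProfile` of the comparison dataset.
#' @param target_cluster cluster expected to share the program.
#' @param fold linear fold threshold (strict on log2 scale; default 2).
#' @return The shared upregulated subset of `markers`.
#' @export
shared_upregulated <- function(markers, other_profile, target_cluster,
                               fold = 2.0) {
  if (!target_cluster %in% rownames(other_profile$means))
    input_error(sprintf("cluster '%s' absent from profile", target_cluster))
  present <- markers[markers %in% colnames(other_profile$means)]
  if (!length(present)) return(character())
  m <- other_profile$means[, present, drop = FALSE]
  target <- m[target_cluster, ]
  others <- m[rownames(m) != target_cluster, , drop = FALSE]
  max_other <- if (nrow(others)) apply(others, 2, max) else rep(-Inf, ncol(m))
  present[target - max_other > log2(fold)]
}

#' Markers specific to one dataset's cluster and silent in the other's
#'
#' Keeps markers highly expressed in the source cluster (mean log2 value
#' strictly above `hi`) but weakly expressed in the matched cluster of the
#' comparison dataset after cross-platform adjustment (strictly below
#' `lo`). This is the selection that yielded the 110 genes high in T1LCs
#' but low in oogonia-like cells (T1LC mean log2\[TPM+1\] > 4, adjusted
#' log2\[RPM+1\] < 2).
#'
#' @param markers character marker set.
#' @param source_means per-gene means in the source cluster: a named
#'   numeric vector, or a `ClusterProfile` with `source_cluster`.
#' @param adjusted_means per-gene adjusted means in the comparison
#'   cluster: a named numeric vector, or a `ClusterProfile` with
#'   `other_cluster`. Must already be on the adjusted scale (see
#'   [apply_adjustment()]).
#' @param hi,lo expression thresholds (both strict; defaults 4 and 2).
#' @param source_cluster,other_cluster cluster names when profiles are
#'   passed.
#' @return The specific subset of `markers`.
#' @export
t1lc_specific <- function(markers, source_means, adjusted_means,
                          hi = 4.0, lo = 2.0,
                          source_cluster = NULL, other_cluster = NULL) {
  sm <- profile_vector(source_means, source_cluster)
  am <- profile_vector(adjusted_means, other_cluster)
  present <- markers[markers %in% names(sm) & markers %in% names(am)]
  present[sm[present] > hi & am[present] < lo]
}
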