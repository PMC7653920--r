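# Study-condition builders shared by the acceptance suite. Conditions are
# fixed design choices (see the methods vignette): 6 developmental stages x
# 200 cells, 2000 genes with log-normal baselines, 50 markers planted at
# 2-8 fold on moderately expressed genes so planted counts remain a
# negligible fraction of each cell's library.

deg_study_conditions <- function(seed) {
  clusters <- c("hiPSC", "iMeLC", "hPGCLC", "MLC", "TC", "T1LC")
  base <- withr::with_seed(seed, rlnorm(2000, log(5), 1))
  eligible <- which(base >= 5 & base <= 10)
  markers <- data.frame(
    feature = sprintf("gene%04d", eligible[1:50]),
    cluster = rep(clusters, length.out = 50),
    effect = withr::with_seed(seed + 1, runif(50, 1, 3)))
  list(clusters = clusters, base = base, markers = markers)
}

simulate_deg_study <- function(conditions, seed, with_markers = TRUE) {
  cfg <- sim_config(cluster_names = conditions$clusters, n_cells = 200,
                    n_genes = 2000, baseline_mean = conditions$base,
                    dispersion = 2,
                    marker_spec = if (with_markers) conditions$markers,
                    seed = seed)
  normalize_counts(filter_genes(simulate_counts(cfg)$matrix), "tpm")
}

# pairwise DEG recovery over all cluster pairs; the calling fold gate sits
# below the smallest planted effect so 2-fold markers are detectable
pairwise_recovery <- function(norm, conditions, fold = 1.5) {
  clusters <- conditions$clusters
  ms <- conditions$markers
  recovered <- 0; tested <- 0; tp <- 0; fp <- 0
  for (i in seq_len(length(clusters) - 1)) {
    for (j in seq(i + 1, length(clusters))) {
      a <- clusters[i]; b <- clusters[j]
      res <- pairwise_deg(norm, a, b, min_mean = 2, fold = fold,
                          fdr_threshold = 0.01)
      ma <- ms$feature[ms$cluster == a]; mb <- ms$feature[ms$cluster == b]
      recovered <- recovered +
        sum(res$deg[match(ma, res$feature_id)] == "a", na.rm = TRUE) +
        sum(res$deg[match(mb, res$feature_id)] == "b", na.rm = TRUE)
      tested <- tested + sum(ma %in% res$feature_id) + sum(mb %in% res$feature_id)
      true_call <- (res$deg == "a" & res$feature_id %in% ma) |
        (res$deg == "b" & res$feature_id %in% mb)
      tp <- tp + sum(true_call)
      fp <- fp + sum(res$deg != "none" & !true_call)
    }
  }
  list(sensitivity = recovered / tested, tp = tp, fp = fp,
       fdp = fp / max(tp + fp, 1))
}

multigroup_recovery <- function(norm, conditions) {
  ms <- conditions$markers
  mk <- multigroup_markers(norm)        # the paper's rule: >2-fold, FDR<0.05
  planted <- paste(ms$feature, ms$cluster)
  called <- paste(mk$feature_id, mk$cluster)
  list(sensitivity = mean(planted %in% called),
       fp = sum(!called %in% planted), n_calls = nrow(mk),
       fdp = sum(!called %in% planted) / max(nrow(mk), 1))
}

# one replicate of the variable-TE study: 100 subfamilies of 5 loci, one
# subfamily modulated 8-fold across the 6 stages
te_variable_replicate <- function(seed) {
  clusters <- c("hiPSC", "iMeLC", "hPGCLC", "MLC", "TC", "T1LC")
  subfams <- sprintf("SF%03d", 1:100)
  layout <- stats::setNames(lapply(subfams, function(s)
    list(family = "F", te_class = "LTR", n_loci = 5, locus_length = 300)),
    subfams)
  ga <- simulate_genome_annotation(2, 1e6, n_genes = 300, te_layout = layout,
                                   seed = seed)
  program <- lapply(stats::setNames(2^seq(0, 3, length.out = 6), clusters),
                    function(f) c(SF001 = unname(f)))
  cfg <- sim_config(cluster_names = clusters, n_cells = 50, n_genes = 300,
                    n_te_loci = 500,
                    baseline_mean = c(rep(5, 300), rep(2, 500)),
                    dispersion = 5, te_program = program,
                    te_subfamily = rep(subfams, each = 5), seed = seed + 1)
  sim <- simulate_counts(cfg)
  totals <- Matrix::rowSums(sim$matrix$counts)
  te <- sim$matrix
  keep <- te$feature_kind == "te_locus"
  te$counts <- te$counts[, keep, drop = FALSE]
  te$feature_kind <- te$feature_kind[keep]
  te <- filter_te_loci(te)
  sub <- aggregate_te(te, ga$annotation, "subfamily")
  norm <- te_normalize(sub, totals)
  variable_tes(norm, min(100, ncol(norm$values)))
}

# toy genome with three TE subfamilies and planted peak enrichment for two
enrichment_study <- function(seed, n_peaks = 2000, n_iter = 500) {
  layout <- list(A = list(family = "F", te_class = "LTR", n_loci = 40,
                          locus_length = 300),
                 B = list(family = "F", te_class = "LTR", n_loci = 40,
                          locus_length = 300),
                 C = list(family = "F", te_class = "LTR", n_loci = 40,
                          locus_length = 300))
  ga <- simulate_genome_annotation(2, 2e5, n_genes = 0, te_layout = layout,
                                   seed = seed)
  sp <- simulate_peaks(ga$genome, ga$annotation, n_peaks, 200,
                       enrich = c(A = 3, B = 10), seed = seed + 1)
  er <- enrich_subfamilies(sp$peaks, ga$annotation, ga$genome,
                           subfamilies = c("A", "B"),
                           n_iter = n_iter, seed = seed + 2)
  # the null case: a peak set with no planted enrichment anywhere
  sp0 <- simulate_peaks(ga$genome, ga$annotation, n_peaks, 200,
                        enrich = NULL, seed = seed + 3)
  er0 <- enrich_subfamilies(sp0$peaks, ga$annotation, ga$genome,
                            subfamilies = "C",
                            n_iter = n_iter, seed = seed + 4)
  list(genome = ga$genome, annotation = ga$annotation, peaks = sp$peaks,
       enrichment = er, null_fold = er0$fold[1])
}
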