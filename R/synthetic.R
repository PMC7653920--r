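# Synthetic-data generators with planted ground truth. Counts are
# negative binomial (mean/size parameterization), the minimal overdispersed
# model the downstream filters assume; per-cell library sizes are
# log-normal; cluster structure enters as multiplicative shifts of the NB
# mean (2^effect for planted markers, an explicit per-cluster factor for TE
# subfamily programs). Every generator is deterministic under its seed and
# leaves the caller's RNG state untouched.

#' Build a simulation configuration
#'
#' Defines the cluster layout and generative parameters for
#' [simulate_counts()]. Defaults emulate a six-stage in vitro germ-cell
#' specification time course (hiPSC through T1LC).
#'
#' @param cluster_names ordered cluster (stage) names.
#' @param n_cells cells per cluster (recycled if scalar).
#' @param n_genes,n_te_loci number of gene and TE-locus features.
#' @param baseline_mean NB mean per feature before any effect; scalar or
#'   per-feature vector of length `n_genes + n_te_loci`.
#' @param dispersion NB size parameter (smaller = more overdispersed).
#' @param marker_spec data frame (`feature`, `cluster`, `effect`) planting
#'   log2 effects: the feature's mean is multiplied by `2^effect` in that
#'   cluster.
#' @param te_program named list: cluster -> named numeric vector of
#'   multiplicative factors per TE subfamily.
#' @param te_subfamily subfamily assignment per TE locus (recycled;
#'   default one subfamily `"SF1"`).
#' @param libsize_sdlog SD (log scale) of the log-normal per-cell library
#'   size factor; 0 disables library-size variation.
#' @param library_size_factors optional explicit per-cell factors
#'   (overrides `libsize_sdlog`).
#' @param seed integer seed.
#' @return A `SimConfig` list.
#' @export
sim_config <- function(cluster_names = c("hiPSC", "iMeLC", "hPGCLC", "MLC", "TC", "T1LC"),
                       n_cells = 200, n_genes = 1000, n_te_loci = 0,
                       baseline_mean = 5, dispersion = 2,
                       marker_spec = NULL, te_program = NULL,
                       te_subfamily = "SF1", libsize_sdlog = 0.3,
                       library_size_factors = NULL, seed = 1) {
  if (anyDuplicated(cluster_names)) config_error("cluster names must be unique")
  if (dispersion <= 0) config_error("dispersion must be positive")
  if (any(n_cells <= 0) || n_genes <= 0 || n_te_loci < 0)
    config_error("cell and feature counts must be positive")
  if (any(baseline_mean <= 0)) config_error("baseline_mean must be positive")
  if (libsize_sdlog < 0) config_error("libsize_sdlog must be >= 0")
  n_cells <- rep(as.integer(n_cells), length.out = length(cluster_names))
  if (!is.null(marker_spec)) {
    if (!all(c("feature", "cluster", "effect") %in% names(marker_spec)))
      config_error("marker_spec needs columns feature, cluster, effect")
    if (any(!is.finite(marker_spec$effect)))
      config_error("marker effects must be finite")
    if (!all(marker_spec$cluster %in% cluster_names))
      config_error("marker_spec references unknown clusters")
  }
  if (!is.null(te_program)) {
    if (!all(names(te_program) %in% cluster_names))
      config_error("te_program references unknown clusters")
    if (any(unlist(te_program) <= 0))
      config_error("te_program factors must be > 0")
  }
  if (n_te_loci > 0)
    te_subfamily <- rep(te_subfamily, length.out = n_te_loci)
  structure(list(cluster_names = cluster_names, n_cells = n_cells,
                 n_genes = n_genes, n_te_loci = n_te_loci,
                 baseline_mean = baseline_mean, dispersion = dispersion,
                 marker_spec = marker_spec, te_program = te_program,
                 te_subfamily = if (n_te_loci > 0) te_subfamily,
                 libsize_sdlog = libsize_sdlog,
                 library_size_factors = library_size_factors,
                 seed = as.integer(seed)),
            class = "SimConfig")
}

# default feature id builders shared with annotation generation
sim_gene_ids <- function(n) sprintf("gene%04d", seq_len(n))
sim_te_ids <- function(subfamily) {
  idx <- stats::ave(seq_along(subfamily), subfamily, FUN = seq_along)
  sprintf("%s_L%03d", subfamily, idx)
}

#' Simulate a clustered UMI count matrix with planted truth
#'
#' Draws negative-binomial counts with per-cluster means
#' `baseline * 2^effect * te_factor`, scaled by each cell's library-size
#' factor, and returns the matrix (cluster labels populated) together with
#' the planted truth.
#'
#' @param config a [sim_config()].
#' @return List with elements `matrix` (a [count_matrix()]) and `truth`
#'   (planted markers, TE program, library factors, seed).
#' @export
simulate_counts <- function(config) {
  if (!inherits(config, "SimConfig")) config_error("config must be a SimConfig")
  K <- length(config$cluster_names)
  n_feat <- config$n_genes + config$n_te_loci
  feat_ids <- c(sim_gene_ids(config$n_genes),
                if (config$n_te_loci > 0) sim_te_ids(config$te_subfamily))
  kind <- rep(c("gene", "te_locus"), c(config$n_genes, config$n_te_loci))
  base <- rep(config$baseline_mean, length.out = n_feat)

  # cluster x feature multiplier: markers then TE programs
  mult <- matrix(1, K, n_feat, dimnames = list(config$cluster_names, feat_ids))
  if (!is.null(config$marker_spec)) {
    ms <- config$marker_spec
    if (!all(ms$feature %in% feat_ids))
      config_error("marker_spec references unknown features")
    mult[cbind(match(ms$cluster, config$cluster_names),
               match(ms$feature, feat_ids))] <- 2^ms$effect
  }
  if (!is.null(config$te_program) && config$n_te_loci > 0) {
    for (cl in names(config$te_program)) {
      fac <- config$te_program[[cl]]
      hit <- config$te_subfamily %in% names(fac)
      mult[cl, config$n_genes + which(hit)] <-
        mult[cl, config$n_genes + which(hit)] *
        fac[config$te_subfamily[hit]]
    }
  }

  labels <- rep(config$cluster_names, config$n_cells)
  n_cell <- length(labels)
  barcodes <- sprintf("cell%05d", seq_len(n_cell))

  sim <- with_seed(config$seed, {
    lib <- config$library_size_factors
    if (is.null(lib)) lib <- rlnorm(n_cell, 0, config$libsize_sdlog)
    if (length(lib) != n_cell)
      config_error("library_size_factors length must equal total cells")
    mu <- (lib * mult[match(labels, config$cluster_names), , drop = FALSE]) *
      rep(base, each = n_cell)
    counts <- matrix(rnbinom(n_cell * n_feat, mu = as.numeric(mu),
                             size = config$dispersion),
                     n_cell, n_feat, dimnames = list(barcodes, feat_ids))
    list(counts = counts, lib = lib)
  })

  m <- count_matrix(Matrix::drop0(Matrix::Matrix(sim$counts, sparse = TRUE)),
                    feature_kind = kind, cluster_labels = labels)
  list(matrix = m,
       truth = list(markers = config$marker_spec,
                    te_program = config$te_program,
                    te_subfamily = config$te_subfamily,
                    library_size_factors = sim$lib,
                    seed = config$seed))
}

#' Simulate a toy genome with genes and hierarchically grouped TE loci
#'
#' Places genes and TE loci uniformly and without overlap on equal-length
#' chromosomes; TE loci inherit subfamily/family/class from `te_layout`.
#'
#' @param n_chroms number of chromosomes.
#' @param chrom_length length of each chromosome (bases).
#' @param n_genes number of gene features (length `gene_length`).
#' @param te_layout named list: subfamily -> `list(family, te_class,
#'   n_loci, locus_length)`.
#' @param gene_length gene footprint in bases (default 1000).
#' @param seed integer seed.
#' @return List with `annotation` (a [feature_annotation()]) and `genome`
#'   (a [genome_sizes()]).
#' @export
simulate_genome_annotation <- function(n_chroms = 1, chrom_length = 1e6,
                                       n_genes = 0, te_layout = list(),
                                       gene_length = 1000, seed = 1) {
  if (n_chroms <= 0 || chrom_length <= 0) config_error("bad genome dimensions")
  for (sf in names(te_layout)) {
    tl <- te_layout[[sf]]
    if (tl$locus_length < 1 || tl$n_loci < 0)
      config_error("te_layout entries need locus_length >= 1 and n_loci >= 0")
  }
  genome <- genome_sizes(setNames(rep(chrom_length, n_chroms),
                                  sprintf("chr%d", seq_len(n_chroms))))

  ids <- sim_gene_ids(n_genes)
  kinds <- rep("gene", n_genes)
  lens <- rep(gene_length, n_genes)
  sf_of <- rep(NA_character_, n_genes)
  for (sf in names(te_layout)) {
    tl <- te_layout[[sf]]
    sub <- rep(sf, tl$n_loci)
    ids <- c(ids, sim_te_ids(sub))
    kinds <- c(kinds, rep("te_locus", tl$n_loci))
    lens <- c(lens, rep(tl$locus_length, tl$n_loci))
    sf_of <- c(sf_of, sub)
  }
  n_item <- length(ids)

  placed <- with_seed(seed, {
    chrom <- sample(names(genome), n_item, replace = TRUE)
    start <- numeric(n_item)
    for (cn in unique(chrom)) {
      i <- which(chrom == cn)
      free <- chrom_length - sum(lens[i])
      if (free < 0)
        config_error(sprintf("features do not fit on %s: infeasible packing", cn))
      # stars-and-bars: uniform non-overlapping placement of ordered items
      offsets <- sort(sample.int(free + length(i), length(i))) - seq_along(i)
      start[i] <- offsets + c(0, cumsum(lens[i]))[seq_along(i)]
    }
    list(chrom = chrom, start = start,
         strand = sample(c("+", "-"), n_item, replace = TRUE))
  })

  fam <- cls <- rep(NA_character_, n_item)
  te <- kinds == "te_locus"
  fam[te] <- vapply(sf_of[te], function(s) te_layout[[s]]$family, "")
  cls[te] <- vapply(sf_of[te], function(s) te_layout[[s]]$te_class, "")
  ann <- feature_annotation(data.frame(
    feature_id = ids, chrom = placed$chrom, start = placed$start,
    end = placed$start + lens, strand = placed$strand, kind = kinds,
    subfamily = sf_of, family = fam, te_class = cls,
    stringsAsFactors = FALSE))
  list(annotation = ann, genome = genome)
}

# exact per-peak probability that a uniformly placed peak (chromosome
# chosen proportional to admissible starts) overlaps the subfamily's loci
uniform_overlap_prob <- function(index, genome, peak_length) {
  g <- unclass(genome)
  admissible <- pmax(g - peak_length + 1, 0)
  hit_starts <- vapply(names(g), function(cn) {
    ix <- index[[cn]]
    if (is.null(ix)) return(0)
    lo <- pmax(ix$start - peak_length + 1, 0)
    hi <- pmin(ix$end - 1, g[[cn]] - peak_length)
    sum(pmax(hi - lo + 1, 0))
  }, 0)
  sum(hit_starts) / sum(admissible)
}

#' Simulate a peak set with planted subfamily enrichment
#'
#' Places `n_peaks` fixed-length peaks: a computed number is seeded inside
#' loci of each enriched subfamily so that the expected fold-enrichment
#' (under the chromosome- and length-preserving null) is approximately the
#' requested target, and the remainder fall uniformly on the genome
#' (chromosome chosen proportional to admissible starts).
#'
#' @param genome a `Genome`.
#' @param annotation a `FeatureAnnotation` containing the TE loci.
#' @param n_peaks number of peaks.
#' @param peak_length fixed peak width (bases).
#' @param enrich named numeric: subfamily -> target fold (`>= 1`).
#' @param seed integer seed.
#' @return List with `peaks` (an `IntervalSet` with placeholder scores)
#'   and `truth` (per-subfamily target fold, seeded count and per-peak
#'   null overlap probability).
#' @export
simulate_peaks <- function(genome, annotation, n_peaks, peak_length,
                           enrich = NULL, seed = 1) {
  if (any(peak_length > unclass(genome)))
    config_error("peak_length exceeds a chromosome length")
  if (!is.null(enrich) && any(enrich < 1))
    config_error("target folds must be >= 1")
  if (n_peaks == 0) return(list(peaks = empty_interval_set(),
                                truth = list(enriched = NULL, seed = seed)))
  te <- annotation[annotation$kind == "te_locus", , drop = FALSE]
  g <- unclass(genome)

  plan <- data.frame(subfamily = character(), target_fold = numeric(),
                     n_seeded = integer(), p0 = numeric())
  for (sf in names(enrich)) {
    loci <- te[te$subfamily == sf, , drop = FALSE]
    if (!nrow(loci)) config_error(sprintf("no loci for subfamily %s", sf))
    idx <- build_locus_index(interval_set(loci$chrom, loci$start, loci$end))
    p0 <- uniform_overlap_prob(idx, genome, peak_length)
    n_seed <- round((enrich[[sf]] - 1) * p0 * n_peaks / (1 - p0))
    plan <- rbind(plan, data.frame(subfamily = sf, target_fold = enrich[[sf]],
                                   n_seeded = n_seed, p0 = p0))
  }
  if (sum(plan$n_seeded) > n_peaks)
    config_error("requested enrichment needs more seeded peaks than n_peaks")

  peaks <- with_seed(seed, {
    out <- vector("list", nrow(plan) + 1L)
    for (k in seq_len(nrow(plan))) {
      sf <- plan$subfamily[k]; n_seed <- plan$n_seeded[k]
      if (n_seed == 0) next
      loci <- te[te$subfamily == sf, , drop = FALSE]
      pick <- loci[sample.int(nrow(loci), n_seed, replace = TRUE), ]
      lo <- pmax(pick$start - peak_length + 1, 0)
      hi <- pmin(pick$end - 1, g[pick$chrom] - peak_length)
      s <- lo + floor(runif(n_seed) * (hi - lo + 1))
      out[[k]] <- data.frame(chrom = pick$chrom, start = s)
    }
    n_bg <- n_peaks - sum(plan$n_seeded)
    if (n_bg > 0) {
      adm <- pmax(g - peak_length + 1, 0)
      cn <- sample(names(g), n_bg, replace = TRUE, prob = adm)
      s <- floor(runif(n_bg) * adm[cn])
      out[[nrow(plan) + 1L]] <- data.frame(chrom = cn, start = s)
    }
    df <- do.call(rbind, out)
    interval_set(df$chrom, df$start, df$start + peak_length,
                 score = runif(nrow(df)))
  })
  list(peaks = peaks, truth = list(enriched = if (nrow(plan)) plan, seed = seed))
}

#' Simulate a paired expression profile on a distorted second platform
#'
#' Given a per-feature log-expression profile `x`, generates the second
#' platform's profile `y = a*x^2 + b*x + c + N(0, noise_sd)` element-wise:
#' the inverse of the calibration problem [fit_quadratic()] solves.
#'
#' @param base_profile numeric (optionally named) log-expression vector.
#' @param coeffs numeric `c(a, b, c)`.
#' @param noise_sd Gaussian noise SD (`>= 0`; 0 gives the exact curve).
#' @param seed optional integer seed (only needed when `noise_sd > 0`).
#' @return List with `x` (the input) and `y` (the distorted profile).
#' @export
simulate_platform_pair <- function(base_profile, coeffs, noise_sd = 0,
                                   seed = 1) {
  if (length(coeffs) != 3) config_error("coeffs must be c(a, b, c)")
  if (noise_sd < 0) config_error("noise_sd must be >= 0")
  y <- coeffs[1] * base_profile^2 + coeffs[2] * base_profile + coeffs[3]
  if (noise_sd > 0)
    y <- y + with_seed(seed, rnorm(length(base_profile), 0, noise_sd))
  names(y) <- names(base_profile)
  list(x = base_profile, y = y)
}
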