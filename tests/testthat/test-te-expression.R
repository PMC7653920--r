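te_ann <- function() {
  feature_annotation(data.frame(
    feature_id = c("A_L1", "A_L2", "B_L1", "C_L1"),
    chrom = "chr1", start = c(0, 1000, 2000, 3000),
    end = c(500, 1500, 2500, 3500), strand = "+", kind = "te_locus",
    subfamily = c("A", "A", "B", "C"),
    family = c("fam1", "fam1", "fam1", "fam2"),
    te_class = c("LTR", "LTR", "LTR", "LINE")))
}

gene_ann <- function() {
  feature_annotation(data.frame(
    feature_id = c("g1", "g2"), chrom = "chr1",
    start = c(5000, 7000), end = c(6000, 8000), strand = c("+", "-"),
    kind = "gene"))
}

test_that("combined annotation unions records and resolves id collisions", {
  comb <- build_combined_annotation(gene_ann(), te_ann())
  expect_identical(nrow(comb), 6L)
  expect_identical(sum(comb$kind == "te_locus"), 4L)

  tes <- te_ann()
  tes$feature_id[1] <- "g1"    # collide with a gene id
  comb2 <- build_combined_annotation(gene_ann(), tes)
  expect_true("TE:g1" %in% comb2$feature_id)

  genes2 <- gene_ann()
  genes2$feature_id <- c("g1", "TE:g1")  # prefixing cannot disambiguate
  expect_error(build_combined_annotation(genes2, tes),
               class = "scte_integrity_error")
})

test_that("combined annotation round-trips through GTF with hierarchy intact", {
  comb <- build_combined_annotation(gene_ann(), te_ann())
  gtf <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(comb, gtf)
  back <- read_gtf(gtf)
  ord <- match(comb$feature_id, back$feature_id)
  expect_identical(back$subfamily[ord], comb$subfamily)
  expect_identical(back$family[ord], comb$family)
  expect_identical(back$te_class[ord], comb$te_class)
  expect_identical(back$start[ord], as.integer(comb$start))
})

test_that("reads are uniquely assigned; ambiguous and boundary reads drop", {
  ann <- feature_annotation(data.frame(
    feature_id = c("L1", "L2", "g1"), chrom = "chr1",
    start = c(100, 280, 1000), end = c(300, 400, 1200),
    strand = "+", kind = c("te_locus", "te_locus", "gene"),
    subfamily = c("S", "S", NA), family = c("F", "F", NA),
    te_class = c("C", "C", NA)))
  reads <- data.frame(
    barcode = c("c1", "c1", "c2", "c2", "c1", "zz"),
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr9", "chr1"),
    start = c(150, 290, 0, 1000, 150, 150),
    end = c(250, 310, 100, 1100, 250, 250))
  # read2 spans L1 and L2 (ambiguous); read3 ends where nothing starts;
  # read5 unknown chromosome; read6 unknown barcode
  m <- count_assignments(reads, ann, cells = c("c1", "c2"))
  st <- attr(m, "assignment_stats")
  expect_identical(st$assigned, 2L)
  expect_identical(st$discarded_ambiguous, 1L)
  expect_identical(st$assigned + st$discarded_ambiguous +
                     st$discarded_no_overlap + st$discarded_unknown_chrom +
                     st$discarded_unknown_barcode, st$input)
  expect_identical(as.numeric(m$counts["c1", "L1"]), 1)
  expect_identical(as.numeric(m$counts["c2", "g1"]), 1)
  expect_identical(sum(m$counts), 2)
})

test_that("half-open footprints touching a feature boundary do not overlap", {
  ann <- feature_annotation(data.frame(
    feature_id = "L1", chrom = "chr1", start = 200, end = 300, strand = "+",
    kind = "te_locus", subfamily = "S", family = "F", te_class = "C"))
  reads <- data.frame(barcode = "c1", chrom = "chr1", start = 100, end = 200)
  m <- count_assignments(reads, ann, cells = "c1")
  expect_identical(sum(m$counts), 0)
  expect_identical(attr(m, "assignment_stats")$discarded_no_overlap, 1L)
})

test_that("TE detection filter applies the inclusive 0.5% boundary", {
  counts <- matrix(0L, 1000, 3,
                   dimnames = list(sprintf("c%04d", 1:1000), c("L1", "L2", "L3")))
  counts[1:5, 1] <- 1L      # detected in exactly 0.5% of cells: kept
  counts[1:4, 2] <- 7L      # detected in 0.4%: removed
  counts[, 3] <- 1L         # ubiquitous: kept
  m <- count_matrix(counts, feature_kind = "te_locus")
  kept <- filter_te_loci(m)
  expect_identical(feature_ids(kept), c("L1", "L3"))
  expect_identical(feature_ids(filter_te_loci(m, 0)), c("L1", "L2", "L3"))
})

test_that("hierarchy aggregation sums children and conserves totals", {
  counts <- rbind(c(3, 4, 2, 1), c(0, 1, 5, 0))
  rownames(counts) <- c("c1", "c2"); colnames(counts) <- te_ann()$feature_id
  m <- count_matrix(counts, feature_kind = "te_locus")
  sub <- aggregate_te(m, te_ann(), "subfamily")
  expect_identical(as.numeric(sub$counts["c1", "A"]), 7)
  fam <- aggregate_te(m, te_ann(), "family")
  cls <- aggregate_te(m, te_ann(), "class")
  tot <- aggregate_te(m, te_ann(), "total")
  for (agg in list(sub, fam, cls, tot))
    expect_equal(as.numeric(Matrix::rowSums(agg$counts)),
                 as.numeric(Matrix::rowSums(m$counts)))
  expect_identical(n_features(tot), 1L)
  expect_identical(sort(feature_ids(fam)), c("fam1", "fam2"))
})

test_that("subfamilies emptied by locus filtering are absent, not zero rows", {
  counts <- matrix(0L, 1000, 2,
                   dimnames = list(sprintf("c%04d", 1:1000), c("A_L1", "C_L1")))
  counts[1:50, 1] <- 2L
  counts[1, 2] <- 1L        # detected in 0.1%: filtered out
  m <- count_matrix(counts, feature_kind = "te_locus")
  kept <- filter_te_loci(m)
  sub <- aggregate_te(kept, te_ann(), "subfamily")
  expect_identical(feature_ids(sub), "A")
})

test_that("aggregation validates inputs", {
  counts <- matrix(1L, 2, 1, dimnames = list(c("c1", "c2"), "A_L1"))
  mixed <- count_matrix(counts, feature_kind = "gene")
  expect_error(aggregate_te(mixed, te_ann(), "subfamily"),
               class = "scte_input_error")
  orphan <- count_matrix(matrix(1L, 2, 1,
                                dimnames = list(c("c1", "c2"), "X_L9")),
                         feature_kind = "te_locus")
  expect_error(aggregate_te(orphan, te_ann(), "subfamily"),
               class = "scte_integrity_error")
})

test_that("TE normalization uses combined library totals", {
  counts <- matrix(c(20, 10), 2, 1, dimnames = list(c("c1", "c2"), "A"))
  m <- count_matrix(counts, feature_kind = "te_locus")
  norm <- te_normalize(m, cell_totals = c(c1 = 2000, c2 = 1000))
  expect_equal(as.numeric(norm$values[, 1]), c(log2(101), log2(101)),
               tolerance = 1e-12)
  expect_identical(norm$scheme, "cp10k_log2")
  expect_error(te_normalize(m, cell_totals = c(c1 = 2000)),
               class = "scte_integrity_error")
})

test_that("variable-TE ranking orders by variance with deterministic ties", {
  vals <- cbind(hi = c(0, 8, 0, 8), mid = c(1, 3, 1, 3),
                zzz_const = rep(2, 4), aaa_const = rep(5, 4))
  norm <- make_norm(vals)
  colnames(norm$values) <- colnames(vals)
  r <- variable_tes(norm, 4)
  expect_identical(r$feature_id, c("hi", "mid", "aaa_const", "zzz_const"))
  expect_identical(r$variance[3:4], c(0, 0))
  expect_error(variable_tes(norm, 0), class = "scte_config_error")
  expect_error(variable_tes(norm, 5), class = "scte_config_error")
})

test_that("variable-TE ranking is stable under duplication of all cells", {
  withr::with_seed(12, vals <- matrix(rnorm(20 * 30), 20, 30))
  norm1 <- make_norm(vals)
  norm2 <- make_norm(rbind(vals, vals))
  expect_identical(variable_tes(norm1, 30)$feature_id,
                   variable_tes(norm2, 30)$feature_id)
})

test_that("stage dynamics track a planted monotone TE program", {
  stages <- c("hiPSC", "iMeLC", "hPGCLC", "MLC", "TC", "T1LC")
  program <- lapply(setNames(2^seq(0, 3, length.out = 6), stages), function(f)
    c(SF1 = unname(f)))
  cfg <- sim_config(cluster_names = stages, n_cells = 60, n_genes = 150,
                    n_te_loci = 40, baseline_mean = 3, dispersion = 5,
                    te_program = program, seed = 41)
  sim <- simulate_counts(cfg)
  te <- sim$matrix
  keep <- te$feature_kind == "te_locus"
  te$counts <- te$counts[, keep]; te$feature_kind <- te$feature_kind[keep]
  ann <- feature_annotation(data.frame(
    feature_id = feature_ids(te), chrom = "chr1",
    start = seq(0, by = 1000, length.out = 40),
    end = seq(500, by = 1000, length.out = 40), strand = "+",
    kind = "te_locus", subfamily = "SF1", family = "F", te_class = "C"))
  tot <- aggregate_te(te, ann, "total")
  norm <- te_normalize(tot, cell_totals = Matrix::rowSums(sim$matrix$counts))
  dyn <- te_stage_dynamics(norm, stage_order = stages)
  expect_identical(dyn$cluster, stages)
  expect_true(all(diff(dyn$mean) > 0))
})

test_that("stage dynamics handle degenerate clusters", {
  norm <- make_norm(matrix(c(1, 5, 9), 3, 1), labels = c("a", "b", "c"))
  dyn <- te_stage_dynamics(norm, stage_order = c("a", "b", "c"))
  expect_identical(dyn$mean, c(1, 5, 9))
  expect_identical(dyn$n_cells, c(1L, 1L, 1L))

  norm2 <- make_norm(matrix(c(2, 2, 3, 3), 4, 1), labels = rep(c("u", "v"), 2))
  dyn2 <- te_stage_dynamics(norm2)
  expect_identical(dyn2$mean, c(2.5, 2.5))
})
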