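test_that("welch_t matches the closed-form and stats::t.test", {
  # identical samples: no evidence of difference
  r <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_identical(r$t, 0)
  expect_identical(r$p, 1)

  expect_error(welch_t(c(0, 0, 0), c(0, 0, 0)), class = "scte_undefined_error")
  expect_error(welch_t(1, c(1, 2)), class = "scte_input_error")

  # hand computation for x = 1:4, y = 3:6 (equal variances 5/3, n = 4)
  x <- c(1, 2, 3, 4); y <- c(3, 4, 5, 6)
  se2 <- var(x) / 4 + var(y) / 4
  t_hand <- (mean(x) - mean(y)) / sqrt(se2)
  df_hand <- se2^2 / ((var(x) / 4)^2 / 3 + (var(y) / 4)^2 / 3)
  p_hand <- 2 * pt(-abs(t_hand), df_hand)
  r <- welch_t(x, y)
  expect_equal(r$t, t_hand, tolerance = 1e-12)
  expect_equal(r$df, df_hand, tolerance = 1e-12)
  expect_equal(r$p, p_hand, tolerance = 1e-12)

  # independent oracle on random unequal-variance samples
  withr::with_seed(21, {
    for (i in 1:5) {
      a <- rnorm(8, sd = 1); b <- rnorm(13, mean = 0.5, sd = 3)
      ref <- t.test(a, b)
      r <- welch_t(a, b)
      expect_equal(r$t, unname(ref$statistic), tolerance = 1e-10)
      expect_equal(r$df, unname(ref$parameter), tolerance = 1e-10)
      expect_equal(r$p, ref$p.value, tolerance = 1e-10)
    }
  })
})

test_that("bh_adjust equals the direct step-up formula and is permutation-stable", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_identical(bh_adjust(1.0), 1.0)
  expect_error(bh_adjust(c(0.5, 1.2)), class = "scte_input_error")
  expect_error(bh_adjust(c(0.5, NA)), class = "scte_input_error")

  withr::with_seed(33, {
    for (i in 1:10) {
      p <- runif(sample(3:200, 1))^sample(1:3, 1)
      expect_equal(bh_adjust(p), bh_direct(p), tolerance = 1e-12)
      perm <- sample(length(p))
      expect_equal(bh_adjust(p[perm]), bh_adjust(p)[perm], tolerance = 1e-12)
    }
  })
})

test_that("pairwise DEG rule combines abundance, fold and FDR criteria", {
  labels <- rep(c("a", "b"), each = 30)
  withr::with_seed(9, {
    vals <- cbind(
      f1 = c(rnorm(30, 5, 0.2), rnorm(30, 2, 0.2)),   # clear DEG for a
      f2 = c(rnorm(30, 1.9, 0.05), rnorm(30, 0, 0.05)), # abundance fails
      f3 = c(rnorm(30, 5, 0.2), rnorm(30, 4, 0.2)),   # fold fails (delta 1)
      f4 = c(rnorm(30, 3, 0.2), rnorm(30, 6, 0.2)))   # DEG for b
  })
  norm <- make_norm(vals, labels = labels)
  res <- pairwise_deg(norm, "a", "b")
  expect_identical(res$deg, c("a", "none", "none", "b"))
  expect_false(res$pass_abundance[2])   # upregulated mean 1.9 not > 2
  expect_false(res$pass_fold[3])        # delta ~1 below log2(4)
})

test_that("degenerate thresholds partition all features by sign of delta", {
  labels <- rep(c("a", "b"), each = 15)
  withr::with_seed(14, {
    vals <- matrix(rnorm(30 * 40), 30, 40) +
      rep(rep(c(0.3, -0.3), 20), each = 30) * rep(c(1, -1), each = 15)
  })
  norm <- make_norm(vals, labels = labels)
  res <- pairwise_deg(norm, "a", "b", min_mean = -Inf, fold = 1,
                      fdr_threshold = 1 + 1e-9)
  expect_true(all(res$deg != "none"))
  expect_identical(res$deg == "a", res$delta_log2 > 0)
})

test_that("zero-variance features receive p = 1 and stay uncalled", {
  labels <- rep(c("a", "b"), each = 10)
  vals <- cbind(f1 = rep(c(5, 1), each = 10), f2 = rnorm(20))
  norm <- make_norm(vals, labels = labels)
  res <- pairwise_deg(norm, "a", "b")
  expect_identical(res$p_value[1], 1)
  expect_identical(res$deg[1], "none")
})

test_that("multigroup markers recover a planted effect and respect the argmax rule", {
  ms <- data.frame(feature = c("gene0001", "gene0002"),
                   cluster = c("T1LC", "hiPSC"), effect = c(3, 3))
  cfg <- sim_config(cluster_names = c("hiPSC", "MLC", "T1LC"), n_cells = 100,
                    n_genes = 200, baseline_mean = 8, marker_spec = ms,
                    seed = 17)
  sim <- simulate_counts(cfg)
  norm <- normalize_counts(sim$matrix, "tpm")
  mk <- multigroup_markers(norm)
  expect_identical(mk$cluster[mk$feature_id == "gene0001"], "T1LC")
  expect_identical(mk$cluster[mk$feature_id == "gene0002"], "hiPSC")
  # a feature marks at most one cluster
  expect_false(anyDuplicated(mk$feature_id) > 0)
  expect_error(multigroup_markers(norm, labels = rep("one", n_cells(norm))),
               class = "scte_input_error")
})

test_that("identical cluster distributions yield no marker excess", {
  cfg <- sim_config(cluster_names = c("u", "v"), n_cells = 120, n_genes = 400,
                    baseline_mean = 6, seed = 23)
  sim <- simulate_counts(cfg)
  norm <- normalize_counts(sim$matrix, "tpm")
  mk <- multigroup_markers(norm, fold = 1, fdr_threshold = 0.05)
  # every call has raw p <= 0.05; bound false calls by the binomial envelope
  expect_lte(nrow(mk), qbinom(0.999, 2 * 400, 0.05))
})

test_that("cluster profiles average within clusters and r2 behaves", {
  labels <- rep(c("a", "b"), each = 3)
  vals <- matrix(c(1, 1, 1, 5, 5, 5,
                   2, 2, 2, 2, 2, 2), 6, 2)
  norm <- make_norm(vals, labels = labels)
  prof <- cluster_profile(norm)
  expect_equal(unname(prof$means["a", ]), c(1, 2))
  expect_equal(unname(prof$means["b", ]), c(5, 2))
  expect_identical(unname(prof$n_cells["a"]), 3)

  withr::with_seed(2, a <- rnorm(1000))
  expect_equal(profile_r2(a, a), 1, tolerance = 1e-12)
  expect_equal(profile_r2(a, 2 * a + 1), 1, tolerance = 1e-12)
  withr::with_seed(3, {
    x <- rnorm(10000); y <- rnorm(10000)
  })
  expect_lt(profile_r2(x, y), 0.01)
  expect_error(profile_r2(rep(1, 5), rnorm(5)), class = "scte_undefined_error")
  # named profiles align on shared features
  expect_equal(profile_r2(c(g1 = 1, g2 = 2, g3 = 3),
                          c(g3 = 6, g2 = 4, g1 = 2, g9 = 0)), 1,
               tolerance = 1e-12)
})

test_that("expressed-panel selection keeps genes above the floor in any cluster", {
  means <- rbind(c1 = c(gA = 0.2, gB = 0.5, gC = 1.0, gD = 3),
                 c2 = c(gA = 1.2, gB = 0.9, gC = 0.8, gD = 0))
  prof <- make_profile(means)
  expect_identical(select_expressed_panel(prof, c("gA", "gB", "gC", "gD")),
                   c("gA", "gD"))     # gC max is exactly 1.0: strict > drops it
  expect_identical(select_expressed_panel(prof, c("gX", "gY")), character())
  expect_error(select_expressed_panel(prof, character()),
               class = "scte_input_error")
})

test_that("shared upregulation requires a margin over every other cluster", {
  means <- rbind(target = c(g1 = 4.0, g2 = 4.0, g3 = 2.0),
                 other1 = c(g1 = 2.9, g2 = 3.5, g3 = 1.0),
                 other2 = c(g1 = 1.0, g2 = 1.0, g3 = 1.0))
  prof <- make_profile(means)
  # g1: margin 1.1 > 1 keeps; g2: margin 0.5 drops; g4 absent is excluded
  expect_identical(shared_upregulated(c("g1", "g2", "g4"), prof, "target"),
                   "g1")
  # fold = 1: any strictly maximal target mean passes
  expect_identical(shared_upregulated(c("g1", "g2", "g3"), prof, "target",
                                      fold = 1), c("g1", "g2", "g3"))
  expect_error(shared_upregulated("g1", prof, "absent"),
               class = "scte_input_error")
})

test_that("platform-specific marker selection applies strict hi/lo cutoffs", {
  male <- c(g1 = 4.5, g2 = 4.5, g3 = 4.0, g4 = 8)
  female <- c(g1 = 1.5, g2 = 2.5, g3 = 0.0, g4 = 1.9)
  # g1 kept; g2 fails lo; g3 fails strict hi (4.0 not > 4); g5 absent
  expect_identical(t1lc_specific(c("g1", "g2", "g3", "g4", "g5"),
                                 male, female), c("g1", "g4"))
  prof <- make_profile(rbind(T1LC = male))
  expect_identical(t1lc_specific(c("g1", "g2"), prof, female,
                                 source_cluster = "T1LC"), "g1")
})

test_that("selection outputs are subsets of the input marker set", {
  withr::with_seed(44, {
    means <- matrix(runif(5 * 50, 0, 6), 5, 50,
                    dimnames = list(paste0("cl", 1:5), paste0("g", 1:50)))
  })
  prof <- make_profile(means)
  markers <- paste0("g", seq(1, 50, by = 3))
  up <- shared_upregulated(markers, prof, "cl1")
  expect_true(all(up %in% markers))
  spec <- t1lc_specific(markers, means["cl1", ], means["cl2", ])
  expect_true(all(spec %in% markers))
})
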