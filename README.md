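# scTEtools

Single-cell gene **and** transposable-element (TE) expression profiling for
germ-cell development studies.

Characterizing how human prospermatogonia arise — in fetal testes and in
stem-cell-derived reconstitution systems — requires an analysis layer that
standard single-cell toolchains only partly provide: strict multi-criteria
differential-expression rules between developmental stages, a way to put
two scRNA-seq platforms on a comparable expression scale, quantification of
TE expression at individual locus resolution with aggregation up the
RepeatMasker hierarchy (subfamily → family → class), and a randomization
statistic for asking whether chromatin-accessibility peaks fall inside a TE
subfamily more often than chance. scTEtools implements that layer as
tested, reusable R functions, together with synthetic-data generators that
plant known ground truth so every stage can be validated end to end without
any external download.

## The statistics at the core

* **Pairwise DEGs** between cell groups a and b: a feature is called for
  group a iff mean log2(TPM+1) in a is > 2, the difference of group means
  Δ = mean_a − mean_b satisfies Δ ≥ log2(4), and Welch's t-test with
  Benjamini–Hochberg correction across all tested features gives
  FDR < 0.01. "TPM" is length-free counts-per-million, the appropriate
  reading for 3'-UMI counts.
* **Multi-group markers**: one-vs-rest tests per cluster, BH within each
  comparison, marker iff FDR < 0.05 and the cluster mean exceeds the rest
  by more than log2(2); a feature marks only the cluster maximizing its
  mean.
* **Cross-platform adjustment**: ordinary least squares of one platform's
  pseudo-bulk log expression on the monomial basis {x², x, 1} of the
  other's, applied element-wise (y = a·x² + b·x + c).
* **TE profiling**: reads are assigned to the unique overlapping feature
  of a combined gene+TE annotation (ambiguous reads discarded), loci
  detected in ≥ 0.5% of cells are kept, counts are summed up the
  hierarchy, normalized as log2(CP10k + 1) against combined library
  sizes, and subfamilies are ranked by variance across cells.
* **Peak–TE fold enrichment**: observed = number of peaks overlapping
  ≥ 1 locus of a subfamily; the null re-places each peak uniformly on its
  own chromosome with length preserved; fold = observed / mean(null) with
  an add-one empirical p-value.

## Worked example

Simulate a six-stage differentiation time course with two planted marker
genes and a TE subfamily program, then run the pipeline:

```r
library(scTEtools)

cfg <- sim_config(
  n_cells = 100, n_genes = 500, n_te_loci = 50,
  te_subfamily = rep(sprintf("SF%02d", 1:10), each = 5),
  marker_spec = data.frame(feature = c("gene0005", "gene0012"),
                           cluster = c("T1LC", "hPGCLC"), effect = c(3, 2)),
  te_program = list(T1LC = c(SF01 = 6)), seed = 42)
sim <- simulate_counts(cfg)
sim$matrix
#> CountMatrix: 600 cells x 550 features (500 genes, 50 TE loci)
#> clusters: hiPSC (100), hPGCLC (100), iMeLC (100), MLC (100), T1LC (100), TC (100)

m    <- filter_genes(filter_cells(sim$matrix, min_genes = 100))
norm <- normalize_counts(m, "tpm")

deg <- pairwise_deg(norm, "T1LC", "hiPSC")
subset(as.data.frame(deg), deg != "none",
       select = c(feature_id, mean_a, mean_b, delta_log2, fdr))
#>     feature_id mean_a mean_b delta_log2      fdr
#> 5     gene0005   13.2   9.57       3.66 8.67e-17
#> 501  SF01_L001   13.0   9.35       3.67 1.20e-15
#> 502  SF01_L002   12.8   9.68       3.12 3.28e-14
#> 503  SF01_L003   12.9  10.04       2.85 3.02e-16
#> 504  SF01_L004   13.1   9.52       3.56 3.02e-16
#> 505  SF01_L005   12.8   9.78       3.05 2.77e-13
```

The T1LC-vs-hiPSC comparison recovers exactly the planted signal: the
marker gene planted at 8-fold in T1LC (`gene0005`, Δ ≈ 3.7 on the log2
scale) and all five loci of the TE subfamily whose program multiplies
T1LC expression 6-fold. The 4-fold marker of hPGCLC is, correctly,
absent from this comparison. The one-vs-rest marker table attributes the
same features to T1LC:

```r
mk <- multigroup_markers(norm)
head(mk[order(mk$fdr), ], 3)
#>    feature_id cluster mean_in mean_rest delta_log2  p_value      fdr
#> 7   SF01_L001    T1LC    13.0      9.67       3.36 8.84e-61 4.86e-58
#> 10  SF01_L004    T1LC    13.1      9.49       3.60 1.07e-59 2.94e-57
#> 4    gene0005    T1LC    13.2      9.72       3.51 3.48e-55 6.39e-53
```

Applying a previously fitted cross-platform calibration:

```r
fit <- poly_fit(0.0908, -0.0454, 0.1243)
apply_adjustment(fit, 2)
#> [1] 0.3967
```

A thin command-line wrapper over the same functions (subcommands
`simulate`, `qc`, `deg`, `markers`, `xadjust`, `te-aggregate`, `enrich`)
is installed at `inst/scripts/scte-cli.R`.

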