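# radrobust

Cross-software robustness screening for radiomic features.

## The problem

Radiomic pipelines turn a segmented lesion on a CT (or MR/PET) scan into
hundreds of quantitative descriptors: first-order intensity statistics,
shape, texture-matrix features (GLCM, GLRLM, GLSZM, GLDM, NGTDM) and their
wavelet-filtered variants. Before any of these can be trusted as an imaging
biomarker, two robustness questions must be answered:

1. **Repeatability within one platform** — if the same lesion is segmented
   several times with slightly different manual initializations, does the
   feature come back the same?
2. **Reproducibility across platforms** — do two independent,
   IBSI-compliant extraction programs, run on identical images and masks,
   agree on the feature's value and on its relationships to other features?

`radrobust` implements a multi-stage screen that answers both and distils a
compact, non-redundant panel of transferable features. It is aimed at
quantitative-imaging researchers who have lesion-by-feature tables exported
from two extraction platforms (plus repeated-segmentation tables for a
subset of lesions) and need a defensible, reproducible feature shortlist
before modeling.

## The method

**Stage 1 — reliability gate.** Per feature, the intraclass correlation
ICC(A,1) (two-way model, single measurement, absolute agreement) over `n`
subjects and `k` repeated segmentations:

    ICC(A,1) = (MSR − MSE) / (MSR + (k−1)·MSE + k·(MSC − MSE)/n)

with MSR/MSC/MSE the between-subject, between-measurement and residual mean
squares. Features with ICC(A,1) ≥ 0.75 ("good" or better) are retained, per
platform; the cross-platform stage consumes the intersection by default.

**Stage 2 — feature grouping.** Feature–feature dissimilarities under five
metrics — Pearson and Spearman correlation distances `d = sqrt(2(1 − r))`,
and Euclidean, Manhattan and cosine distances between (z-scored) feature
vectors across lesions — feed agglomerative hierarchical clustering under
five linkages (ward.D2, average, complete, single, centroid). The number of
clusters `k` is chosen by majority rule over internal validity indices
(silhouette, Dunn, Calinski–Harabasz) scanned over `k = 2..10`, with an
early stop when index agreement stays low.

**Stage 3 — stability gate.** For every (metric, linkage) configuration the
two platforms are clustered independently and compared with the Adjusted
Rand Index; configurations with **ARI ≥ 0.8** are stable. Degenerate
partitions (one giant cluster plus singletons) are flagged.

**Stage 4 — Composite Index.** Per feature `f`: inter-platform Pearson
correlation `r_f`, two-sample Kolmogorov–Smirnov statistic `D_f`, and mean
fractional ratio `MFR_f = |log((|mean_A|+ε)/(|mean_B|+ε))|`. Each is
standardized by a robust z-score (median/MAD) across the feature cohort and

    CI_f = z_corr,f − z_KS,f − z_MFR,f

so high correlation, low distributional divergence and low scale bias score
high. Within each cluster of each stable solution the top-CI feature is the
**winner** (near-winners trail by ≤ 0.5 z-units); quality-control filters
drop winners with `r_f < 0.6` and greedily remove within-cluster pairs
correlated above 0.9. Winner counts are aggregated across all stable
solutions into a frequency table.

## Worked example

Simulated world with known ground truth: 100 lesions × 60 features in 6
correlated blocks, one planted robust feature per block, every competitor
corrupted on platform B (scale bias, monotone nonlinearity, or heavy
noise):

```r
library(radrobust)
cfg <- sim_config(n_lesions = 100, n_features = 60, n_blocks = 6, seed = 42)
sim <- simulate_platform_pair(cfg)
scr <- icc_screen(simulate_repeated_measures(cfg, sim$truth)$measurements)
head(scr, 3)
#>                     feature       icc  category retained
#>  original_firstorder_sim001 0.9506390 excellent     TRUE
#>     wavelet_lll_glcm_sim002 0.8414275      good     TRUE
#>    wavelet_llh_glrlm_sim003 0.8590206      good     TRUE

pc <- pipeline_config(simulate = cfg,
                      metrics = c("pearson", "spearman", "euclidean"),
                      linkages = c("ward.D2", "average", "complete"))
res <- run_pipeline(pc, "run_out")
res$grid
#> <stability_grid> 9 configurations | 9 stable at ARI >= 0.8 | k policy: per_platform
#>      metric  linkage k_a k_b ari silhouette_a silhouette_b stable
#> 1   pearson  ward.D2   6   6   1        0.519        0.336   TRUE
#> 2   pearson  average   6   6   1        0.519        0.336   TRUE
#> ...

head(res$frequencies, 6)
#>                        feature n_winner n_winner_or_near
#>     original_firstorder_sim001        9                9
#>       wavelet_hll_glrlm_sim051        9                9
#>        wavelet_lhh_gldm_sim041        9                9
#>  wavelet_lhl_firstorder_sim031        9                9
#>       wavelet_llh_glrlm_sim021        9                9
#>        wavelet_lll_gldm_sim011        9                9
```

Reading the output: every ICC passed the 0.75 gate (the generator's true
ICCs are 0.95/0.85); both platforms recover the 6 planted blocks (`k_a =
k_b = 6`) and agree perfectly on the grouping (ARI = 1), so all 9
configurations clear the 0.8 stability gate; and the 6 features winning in
all 9 solutions are exactly the 6 planted robust features — the corrupted
competitors never win. `run_out/` holds every intermediate (ICC tables,
stability grid, per-feature robustness records, winners, frequencies) plus
a `manifest.json` whose hashes are byte-identical across reruns with the
same seed.

With real data, replace `simulate` with file paths:

```r
pc <- pipeline_config(platform_a = "syngo_features.csv",
                      platform_b = "pyradiomics_features.csv",
                      repeated_a = "repeats_syngo.csv",
                      repeated_b = "repeats_pyradiomics.csv")
run_pipeline(pc, "run_out")
```

A command-line driver with `simulate`, `icc`, `cluster`, `stability`,
`select` and `run` subcommands (YAML config) is installed at
`system.file("cli", "radrobust.R", package = "radrobust")`.

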