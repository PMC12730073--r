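---
title: "Methods: cross-software robustness screening for radiomic features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-software robustness screening for radiomic features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radrobust)
```

## Overview and assumptions

`radrobust` screens radiomic features for robustness in two senses:
*repeatability* (the same platform, repeated segmentations of the same
lesions) and *reproducibility* (two extraction platforms, identical lesions
and masks). The unit of observation is the **lesion**, not the patient:
when a patient contributes several lesions each is a separate row, and no
patient-level aggregation is attempted. All stages assume complete numeric
feature vectors; features with missing values after alignment are excluded
and reported rather than imputed, because every downstream formula
(correlations, ECDF distances, cluster dissimilarities) assumes complete
data.

## Stage 1: reliability gate

For each feature, a subjects x repetitions matrix enters a two-way ANOVA
decomposition and

$$\mathrm{ICC}(A,1) = \frac{MSR - MSE}{MSR + (k-1)MSE + k(MSC - MSE)/n}$$

with $MSR$, $MSC$, $MSE$ the between-subject, between-measurement and
residual mean squares. The absolute-agreement form charges systematic
shifts between repetitions ($MSC$) as disagreement, which is the right
convention when repetitions are supposed to be interchangeable
re-measurements.

Conventions adopted:

* Category bands are closed on the left — poor $<0.50$, moderate
  $[0.50, 0.75)$, good $[0.75, 0.90)$, excellent $\ge 0.90$ — so that the
  retention rule "ICC $\ge 0.75$" coincides exactly with "good or better".
* Zero-variance matrices make the ratio 0/0; such features are flagged
  `undefined` and **never retained** (a constant feature carries no
  information, and retaining it would propagate an arbitrary convention).
* Each platform is screened independently; the cross-platform stage
  consumes the **intersection** of retained sets by default. Whether a
  feature must pass on both platforms is a design choice the gate exposes
  (`combine_retained()` also offers union and single-platform modes)
  because study designs differ in which platform "owns" the repeats.

## Stage 2: distances and clustering

Five feature-feature dissimilarities are supported. The correlation
distances $d = \sqrt{2(1-r)}$ (Pearson, Spearman with average ranks) map
$r = 1, 0, -1$ to $d = 0, \sqrt 2, 2$ and embed the correlation structure
isometrically in Euclidean space, which is what licenses variance-based
linkages on them. Euclidean, Manhattan and cosine distances compare feature
columns across lesions.

**Standardization.** Raw radiomic features span orders of magnitude
(volumes in the thousands, normalized uniformities below 1), so geometric
distances on raw columns are dominated by whichever feature is largest. The
package therefore defaults to z-scoring columns before
euclidean/manhattan/cosine (a no-op choice for the correlation metrics,
which are affine-invariant). The flag is recorded in every output because
it changes partitions; both modes are supported as the choice is not
externally dictated.

**Clustering** is agglomerative with the Lance-Williams recurrence for
ward.D2, average (UPGMA), complete, single and centroid linkage. The
implementation is authored in-package rather than delegated, for two
reasons: merge ties break deterministically toward the lowest cluster-slot
pair (column-major scan), making partitions reproducible across platforms
and input orderings; and dendrogram cuts are by merge order, which stays
well defined when centroid linkage produces its characteristic height
inversions (a merge-order cut is the standard resolution). ward.D2 and
centroid assume Euclidean-compatible input; they are allowed on the
correlation distances (which are Euclidean embeddings by construction) and
accepted with a recorded warning on manhattan/cosine, where they are
exploratory.

**Choice of k.** Three internal indices are computed per candidate k:
silhouette (singletons score 0 by the usual convention), Dunn (minimum
inter-cluster distance over maximum diameter) and Calinski-Harabasz. CH is
evaluated from the distance matrix alone through the Euclidean
sum-of-squares identity $SS_C = \sum_{i<j \in C} d_{ij}^2 / |C|$, which
makes it exact for Euclidean-compatible metrics and a reasonable surrogate
otherwise. Each index votes its argmax over the scanned range (default
2..10) and the consensus is the modal vote; ties break toward smaller k
(parsimony). The early-stop rule — halt after `patience = 3` consecutive k
values whose running majority support stays below `threshold = 0.5` — caps
the scan cost on structureless inputs. The 2..10 range and the early-stop
constants are not externally prescribed; they are package defaults, echoed
verbatim into every report so a run is interpretable without the code.

## Stage 3: cross-platform stability

Each (metric, linkage) cell clusters the two platforms independently and
compares partitions with the Hubert-Arabie Adjusted Rand Index. By default
each platform uses its own consensus k (`k_policy = "per_platform"`; ARI is
well defined between partitions of different k); a `"common"` mode forces
platform A's k on both sides, since published workflows are often silent on
whether k was shared and the two choices can differ materially. The gate is
ARI $\ge 0.8$, boundary inclusive. Degenerate partitions — one giant
cluster plus singletons, the classic single-linkage chaining outcome, which
can show near-perfect internal compactness while being scientifically
empty — are flagged per cell; no formal degeneracy rule exists in the
literature this workflow follows, so the flag is advisory rather than a
filter.

## Stage 4: Composite Index and selection

Per feature: inter-platform correlation $r_f$ (Pearson by default; Spearman
offered since rank agreement is sometimes the better-behaved notion),
two-sample KS statistic $D_f$, and the mean fractional ratio. The MFR is
specified only as "a stabilized log-ratio of means"; the package adopts

$$\mathrm{MFR}_f = \left|\log\frac{|\bar x_A| + \varepsilon}{|\bar x_B| + \varepsilon}\right|,
\qquad \varepsilon = 10^{-6}$$

so 0 means no scale bias, the statistic is defined at zero means, and the
signed version (bias direction) is kept in a sidecar column. The magnitude
(not the signed value) is standardized, so that the subtraction in

$$CI_f = z_{corr,f} - z_{KS,f} - z_{MFR,f}$$

penalizes *any* scale bias; using signed values would reward bias in one
direction. The z-scores are robust (median/MAD with an IQR fallback, zeros
when both scales vanish) and are computed across the feature cohort that
actually enters this stage (post-ICC, post-alignment), since the CI is a
relative ranking within a clustering solution, not an absolute calibration.
A consequence worth noting: when the two platforms agree perfectly, all
three statistics are constant across features, every $CI_f$ is exactly 0
and the result is flagged degenerate — the CI cannot rank features that are
all perfect.

Winners are per-cluster CI argmaxes (exact ties: lexicographically smallest
name wins, all tied features reported as co-winners, so that the result is
deterministic and no tie is silently hidden). Near-winners trail the winner
by at most `delta = 0.5` robust-z units. An optional absolute CI floor is
exposed (`ci_floor`) because "exceeding a predefined stability threshold"
can be read as an absolute cutoff in addition to the argmax; by default the
floor is off. QC filters: minimum inter-platform correlation 0.6, then a
greedy (descending CI) intra-cluster redundancy filter at |r| > 0.9,
computed on platform A's values — at the ARI gate the platforms'
correlation structures are near-identical, so the choice of side is
immaterial and is recorded. Winner selection likewise operates on platform
A's partition of each stable solution. The near-winner delta and both QC
thresholds are package defaults (the mechanism, not the constants, is
externally specified); all are config fields echoed into reports.

Winner frequencies are aggregated across all stable solutions into two
counts per feature: solutions won, and solutions won-or-near-won.

## The synthetic world

The generator states one fixed validation world rather than a tunable
benchmark:

* 100 lesions x 60 features in 6 equal blocks — desk-scale proportions of a
  real two-platform study (about 850 features, 97 lesions) that keep the
  full pipeline under a second per replicate;
* within-block correlation 0.8 via a latent factor per block (feature =
  $\sqrt w\,z_b + \sqrt{1-w}\,\epsilon$), chosen over an explicit
  covariance matrix for O(np) generation and exact control of the
  within-block correlation; 0.8 mirrors the strong redundancy of radiomic
  families (a wavelet sub-band's first-order features correlate highly);
* per-feature location/scale drawn over three orders of magnitude, because
  heterogeneous scales are exactly what the standardization choices must
  survive;
* one planted robust feature per block: platform B re-measures it with
  scale factor in $1 \pm 0.02$ and 5% relative noise (a faithful but not
  bit-identical re-extraction);
* every competitor gets a scale bias from $[0.5, 2]$ and one corruption
  cycled from a menu — cube transform (monotone nonlinearity: hurts $r_f$
  and $D_f$), tanh squash (rank-preserving saturation: hurts $D_f$), heavy
  additive noise (hurts $r_f$), 10x scale (hurts $MFR_f$) — so each CI
  component is exercised separately;
* repeated measures from the two-way model with true ICC 0.95 (robust) /
  0.85 (others), and 60 subjects x 3 repetitions, a representative-subset
  design with three independent segmentations.

What the generator does **not** emulate: real lesion-size and
feature-family covariance structure, heavy-tailed texture distributions,
platform-specific discretization effects, and missingness patterns. A green
test on this world therefore establishes that the machinery is correct and
that the selection logic recovers planted structure under realistic noise —
not that any particular clinical dataset will yield stable configurations.

## Numerical choices and degenerate inputs

* Distance matrices are symmetrized ($d \leftarrow (d + d^T)/2$) and
  correlation values clamped to $[-1, 1]$ before the square root, to keep
  floating-point noise from producing complex numbers or asymmetric input.
* Constant features are excluded per metric (correlation and
  standardization undefined), all-zero vectors per cosine; exclusions are
  reported, never imputed.
* Zero-variance ICC matrices return an undefined flag, not an error or a
  sentinel value.
* ARI with degenerate margins (both partitions trivial) returns 1 when the
  partitions are identical and 0 otherwise, the usual convention when the
  chance-correction denominator vanishes.
* Manifest hashes use md5 over the written CSV/JSON artifacts only;
  timestamps, absolute paths and PNG bytes are excluded so identical
  (config, seed) runs are byte-identical.

## Known limitations

* The consensus-k machinery uses three indices; the index set is pluggable
  but intentionally small, not a re-implementation of a thirty-index
  battery.
* The pure-R agglomeration is $O(n^3)$ worst case with vectorized inner
  loops; it is instant at desk scale and a few seconds at ~850 features,
  but not intended for tens of thousands of items.
* Only ICC(A,1) is implemented — no ICC(C,1)/ICC(A,k), no inter-reader
  designs.
* No additional partition-agreement measures (NMI, VI) and no downstream
  predictive modeling on the selected panel.
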