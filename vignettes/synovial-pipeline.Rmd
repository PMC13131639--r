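---
title: "Methods: consensus subtyping and cartilage-degeneration analysis of synovium"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus subtyping and cartilage-degeneration analysis of synovium}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its statistical methods:
the models, the tunable parameters and why their defaults are what they
are, what the synthetic generators do and do not emulate, and the
numerical conventions that make results reproducible. It states no
empirical claim that the test suite or `scripts/acceptance.R` does not
itself compute.

## 1. The scientific problem

Knee osteoarthritis synovium is molecularly heterogeneous. The pipeline
asks three connected questions. First, do bulk synovial transcriptomes
from arthroplasty patients fall into reproducible molecular clusters?
Second, which synovial genes track the severity of cartilage
degeneration on the damaged femoral condyle (the D-OARSI histologic
score, dichotomized at ≥ 20)? Third, which cell types carry those
signals — addressed with single-cell marker genes and, for transcripts
depleted from dissociation-based datasets (notably adipocyte markers),
with spatial transcriptomics of an intact slide.

## 2. Consensus clustering

`run_consensus` repeats, for each of `n_iterations` resampling
iterations: draw `ceiling(subsample_fraction * n)` samples without
replacement, cluster them at every K in `k_range`, and accumulate
co-cluster and co-sample counts. The consensus entry for a sample pair
is co-cluster / co-sample counts — the fraction of iterations in which
the pair clustered together among iterations sampling both. Defaults
follow the published configuration: 5,000 MAD-selected genes
(`select_variable_genes`; raw MAD, ties broken lexicographically for
determinism), 2,000 iterations, 80% subsampling, K = 2–10.

*Base clusterer.* Unstated in the source analysis; we default to
agglomerative clustering with (1 − Pearson correlation) distance and
average linkage — the dominant convention for this resampling scheme —
with k-means as the configurable alternative. Final assignments are
always called from the consensus matrix itself (average-linkage
hierarchical clustering of 1 − consensus, cut at K), not from any single
base run.

*Undefined pairs.* Pairs never co-sampled have no consensus value; they
are excluded from the CDF and imputed at the neutral 0.5 only for the
final assignment distance. At 2,000 iterations × 80% the probability of
such a pair is negligible (≈ 0.04^2000 per pair).

*K selection.* The CDF of lower-triangle consensus values is evaluated
on the grid 0, 0.01, …, 1; AUC by the trapezoid rule; ΔAUC(K) is the
relative AUC change from K − 1 (and equals AUC at the first K). The
published criterion — "diminishing gains beyond K" — is visual, so
`select_k` is advisory and the full curve is always reported. We
deliberately do **not** use "smallest K whose ΔAUC exceeds the next by
≥ 1.5×": on planted 4-cluster data with one small cluster (6%), the
K2→K3 gain dwarfs K3→K4 and that rule stops one short of the truth.
Instead `select_k` returns the K at which the gain curve flattens most
sharply — maximizing ΔAUC(K)/ΔAUC(K+1) among K whose own gain is still
non-negligible (ΔAUC ≥ `min_delta`, default 0.02, i.e. a 2% relative
AUC improvement). On the planted synthetic world this recovers K = 4;
the recovery is asserted in the acceptance suite (ARI ≥ 0.9 at K = 4 in
≥ 18/20 seeds).

*Randomness.* One master seed spawns a child seed per iteration
(`derive_seeds`), so iteration results are independent of execution
order, and all generators save and restore the global RNG state.

## 3. Differential expression and association tables

The DE engine is a two-sided Wilcoxon rank-sum test per gene on logCPM
(`log2(1e6·count/library + 1)`; pseudocount 1 keeps zeros at exactly 0),
with BH correction and log2FC defined as the mean logCPM difference.
This is a deliberate choice of a distribution-free, exactly reproducible
engine consistent with the study's stated statistical toolbox; the
result contract (gene, log2FC, statistic, p, q, direction) keeps the
engine pluggable should a moderated model be preferred. "Expressed"
means non-zero in ≥ 10% of samples (configurable; unstated in the
source).

The rank-sum implementation enumerates the exact null (dynamic
programming over subset rank sums) when the smaller group has ≤ 12
untied observations, and otherwise uses the normal approximation with
tie and continuity correction; both paths are verified against
brute-force enumeration and base R in the tests. BH is the literal
step-up rule. Note one repair to a stated invariant: BH is *not*
idempotent as a function (re-adjusting q-values can only raise them);
the tests assert the true properties — re-adjustment never loosens, and
thresholding q reproduces the classical step-up decision on raw p.

`associate_metadata` mirrors the clinical-table convention: per
continuous variable, Shapiro-Wilk in every cluster; mean (SD) with
Welch's one-way ANOVA when all clusters look normal (p > 0.05), else
median (p25, p75) with Kruskal-Wallis. Clusters too small or too
discrete to assess (n < 3 or < 3 distinct values) are conservatively
treated as non-normal. Categorical variables use Fisher's exact test —
conditional-hypergeometric exact for 2×2, Monte Carlo over margin-fixed
tables (`r2dtable`, 1e5 draws, +1 pseudocount, fixed seed) beyond that,
since exact network algorithms are out of scope.

## 4. Single-cell markers and bulk interpretation

Cells are normalized to 10,000 counts per cell then `log1p` — the
standard platform default, since the source defers normalization to its
supplement. `sc_markers` tests each gene one-vs-all per type and emits a
marker only when all three published thresholds hold: log2FC ≥ 0.5,
in-type detection ≥ 40%, and detection ≥ 10 points above all other
cells. log2FC uses de-logged normalized means with ε = 1e-9 — the
mean-of-expression convention; the alternative (mean of logs) is common
too, and the choice is flagged here because the source does not state
it. The invariant is directly assertable and asserted: every emitted
marker re-checks against the thresholds.

`loading_enrichment` tests whether a type's markers load coherently on a
bulk principal component (gene-centered SVD, unit-norm loadings, sign
fixed so the largest-magnitude loading is positive) with a two-sided
one-sample signed-rank test, exact by sign-pattern enumeration for
n ≤ 12 (valid under ties in |loadings|).

`marker_score_by_cluster` scores each bulk sample as the mean logCPM of
a type's top markers (`top_n = 20`; "top markers" is unquantified in the
source legend) and compares clusters to a reference by one-way ANOVA
plus many-to-one contrasts. The family-wise adjustment simulates the
max-|t| null directly — group-mean errors N(0, 1/n_j), a shared
chi-square variance draw, contrasts against the shared reference —
which reproduces the classical many-to-one (Dunnett-type) correlation
structure without multivariate-t quadrature. B defaults to 10,000
draws; calibration (family-wise error in (0.03, 0.07) at nominal 0.05
over 2,000 null families) is asserted in the acceptance suite.

## 5. Module scores, smoothing, enrichment

The per-cell degeneration score is the mean normalized expression of the
positively associated gene set minus that of the negatively associated
set. `knn_smooth` replaces each score by the mean over the cell and its
k Euclidean nearest neighbours (default k = 15 in a 20-component PCA
embedding; both unstated in the source and therefore configurable and
logged). Including the cell itself keeps the operator a convex
combination — bounded by the raw extremes and idempotent on constants.
Distance ties break by cell index; one consequence worth stating: for
three collinear cells at 0, 1, 2 with raw scores (0, 3, 6) and k = 1,
the middle cell's neighbour is the *lower-index* cell, giving smoothed
scores (1.5, 1.5, 4.5).

Single-sample set scores use the ssGSEA-style weighted-ECDF statistic
(weights rank^α, α = 0.25, z-rescaled per set across samples) as a
stand-in for GSVA: both are rank-based per-sample scores, the downstream
use is a Spearman correlation against D-OARSI (tie-corrected mid-rank
rho; exact permutation p for n ≤ 9, t-approximation otherwise), and the
kernel is swappable behind the contract. Preranked enrichment is the
classical weighted Kolmogorov-Smirnov running sum (weight |statistic|,
falling back to the unweighted walk when the set's statistics are all
zero), with a gene-permutation null — matching the preranked setting
where only one ranked list exists — NES = ES / mean |same-sign null ES|,
and a +1-pseudocount same-sign tail p.

## 6. Spatial statistics

`composition` reports counts and fractions per cell type within a
region (percentages printed to one decimal). Two reference conventions
coexist deliberately: cell-type fold enrichment defaults to the
*inclusive* whole-slide reference because the published worked example
((17/290)/(82/36,320) ≈ 26) matches that arithmetic, whereas per-gene
zoom enrichment uses the *exclusive* remainder, as described in the
source ("remainder of the tissue"); both are exposed as an argument.
"Gene-positive" means transcript count ≥ 1 (configurable), natural for
in-situ panels. Per-gene 2×2 Fisher tests get BH correction across the
panel; a gene with zero positives anywhere is reported with missing
fold and p = 1 rather than dropped, so the BH family is stable.

## 7. The synthetic world

The generators encode the cohort structure the analyses assume; their
defaults are fixed once and are not tuned to test outcomes.

- **Bulk** (`simulate_bulk`): 135 samples in four clusters at
  proportions 0.29/0.38/0.27/0.06 (the published cluster sizes);
  negative-binomial counts (dispersion 0.15) over log-normal gene means;
  log-normal library sizes with CV 0.3 (typical of bulk RNA-seq;
  unstated in the source); per-cluster marker blocks with a planted
  log2 effect (default 2). D-OARSI is an integer draw on 12–20 weighted
  toward the top (a surgical cohort scores high), +2 in clusters 2–3 —
  the direction of the published cluster-OARSI association — clipped to
  the 0–24 scale; the source reports medians/IQRs, not a generative
  model, so these are stand-ins, not estimates. Cluster 4 carries a
  binary "major trauma" covariate at 38% versus 10% elsewhere to
  exercise the association tests.
- **Single cell** (`simulate_sc`): eight synovial populations at
  plausible proportions; Poisson-lognormal counts (per-cell log-normal
  capture factor, σ = 0.3). Marker genes have baseline rate 0.25 and
  in-type rate 0.25 × `marker_fold` (default 4), putting in-type
  detection near 63% against a ~20% background — satisfying the marker
  thresholds in expectation with margin, as the spec for this world
  requires.
- **Spatial** (`simulate_spatial`): 36,320 cells uniform on a
  4,000 × 3,000 µm slide; type proportions follow the published
  whole-slide composition with adipocytes at 0.23% baseline; a ~310 µm
  square region (≈ 290 expected cells) overrides the adipocyte
  proportion to 6%, other types rescaled to keep the simplex. The gene
  panel is zero-inflated shifted Poisson — with probability p the count
  is 1 + Poisson(μ − 1), else 0 — so detection probabilities are exact
  by construction and the detection-statistics checks have a sharp
  target.

What the generators do **not** emulate: batch effects, doublets,
ambient RNA, read-level noise, gene-gene correlation beyond the planted
blocks, spatial autocorrelation beyond the single enriched region, and
any real biological covariance between the modalities (bulk, single
cell and spatial universes are generated independently). A green test
therefore establishes that the statistical machinery behaves as
specified on data with the assumed structure — not that the published
cohort-level numbers (ΔAUC values, DEG counts, score medians, real-data
correlations) are reproduced; those require the deposited data and are
expressly out of scope.

## 8. Numerical conventions and degenerate inputs

- All tests two-sided; exact small-sample paths switch on automatically
  (rank-sum: min group ≤ 12 and no ties; signed-rank: n ≤ 12; Spearman:
  n ≤ 9; Fisher: any 2×2).
- Constant genes: rank-sum tie correction drives the null variance to
  0; we return p = 1 (and log2FC = 0) rather than NaN.
- Ties: MAD gene ranking, marker ordering and expression ranking all
  break ties by identifier; KNN by cell index — every ordering in the
  package is total, so identical seeds give bit-identical outputs.
- Quantiles are linear-interpolation (type 7) percentiles.
- Dense CSV output writes 17 significant digits so write→read
  round-trips are bit-identical.
- Pipeline configs are JSON rather than YAML (no YAML parser among the
  package's dependencies); the manifest records parameters, derived
  per-stage seeds and MD5 checksums, sufficient to re-execute any stage
  in isolation.

## 9. Known limitations

The DE engine is unmoderated and unadjusted for covariates; Fisher
tests beyond 2×2 are Monte Carlo; ssGSEA stands in for GSVA; cell-type
labels are inputs (no clustering or label transfer); spatial regions
are rectangles or precomputed labels (no polygons). Each limitation is
a contract boundary, not an accident: the corresponding interfaces take
the finished artifact (labels, regions, gene sets) as input.
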