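---
title: "Density-based clustering of connectivity features: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Density-based clustering of connectivity features: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`fcclust` stratifies subjects into diagnostic groups *without* using their
labels: it derives functional-connectivity features from resting-state ROI
time series, clusters subjects with two density-based algorithms (DBSCAN
and OPTICS), and only afterwards compares the clusters with the known
diagnoses via cluster purity. This vignette documents the models, the
tunable parameters, and the design choices that were genuinely open, so
results can be interpreted and reproduced.

## Connectivity features

**Static functional connectivity (SFC).** For each subject, the Pearson
correlation between every pair of ROI time series, giving an
ROI-by-ROI matrix (`static_fc()`); the vectorized upper triangle supplies
one candidate feature per ROI pair.

**Dynamic functional connectivity (DFC) variance.** Sliding-window Pearson
correlation (`sliding_window_corr()`) with stride one timepoint, summarized
by the sample variance over windows (`dfc_variance()`). The variance
measures how much connectivity fluctuates during the scan; it is bounded by
1 because the windowed correlations live in $[-1, 1]$.

**Adaptive window length.** Rather than fixing the window length
arbitrarily, `adf_window_length()` chooses the smallest length $w$ in a
search range such that at least 95% of the length-$w$ windows *reject* the
augmented Dickey-Fuller (ADF) unit-root null at level $\alpha = 0.05$ —
i.e. the smallest window within which the series behave as stationary. One
global length per cohort is computed from a deterministic sample of pooled
ROI series (`choose_window_length()`), keeping DFC features commensurable
across subjects and pairs; per-series lengths remain available through the
single-series function.

Numerical notes on the ADF step, all configurable via `window_spec()`:

* The regression uses a constant and no trend; augmentation lags are chosen
  by AIC in `adf_test()`, but the *window scan* defaults to zero lags:
  power simulations show the Dickey-Fuller test on stationary white noise
  has power about 0.92 at $n = 20$ (less with AIC lags), so a 95%-of-windows
  rule could essentially never accept very short windows. For the same
  reason the default search floor is `min_len = 30` (power ≈ 0.998), with a
  ceiling of 60 timepoints.
* Decisions use tau-mu critical values interpolated in the sample size;
  supported levels are 0.01, 0.05, 0.10.
* A constant (zero-variance) series cannot be tested and is reported as
  non-stationary at the ceiling length.

**Covariate-adjusted selection.** `select_top_features()` fits, per
feature, the linear model `feature ~ group + age + gender + motion` and
ranks features by the p-value of the F-test on the group term — a
mass-univariate analysis of covariance. The multivariate flavour of that
test is deliberately not implemented: the analysis only consumes the
per-feature p-value ranking ("top-k by smallest p"), for which the
mass-univariate F-test is the direct tool. Ties break by feature index so
selection is deterministic; an optional significance gate (`alpha`) and an
optional Fisher z-transform of correlations are off by default.

## DBSCAN and its radius

`run_dbscan()` is a from-scratch implementation of classical DBSCAN under
the Euclidean metric. A point is a *core point* when its
$\varepsilon$-neighborhood — the point itself included — contains at least
`min_pts` points; clusters are the density-connected components of core
points; border points attach to the first cluster whose core point reaches
them in scan order (row order); everything else is an outlier, labeled 0.
Clusters are numbered 1..K in discovery order. No spatial index is used:
at cohort scale ($n \approx 132$) the $O(n^2)$ distance matrix is trivial
and is shared across the radius grid.

The radius is selected in two stages (`epsilon_plot_select()`):

1. **Initial estimate.** The k-distance graph (`k_distance_graph()`, with
   $k =$ `min_pts`) is scanned for its elbow. Because "visual inspection"
   is not reproducible, the elbow is defined as the point of maximum
   perpendicular distance from the chord joining the curve's endpoints
   (kneedle-style); on a perfectly straight curve the tie resolves to the
   middle point.
2. **Epsilon plot.** DBSCAN runs on a uniform grid of 200 radii in
   $(0, 2\hat\varepsilon]$. The cluster count as a function of the radius
   forms a step plot; the widest step with **at least two clusters** is
   selected and its midpoint becomes the final radius. Steps with 0 or 1
   cluster are excluded from the search because an arbitrarily large radius
   always yields one cluster and would otherwise always win; when no
   multi-cluster step exists the widest single-cluster step is used with a
   warning. Ties between equally wide steps resolve to the smaller radius.

`min_pts` defaults to 10 for cohort-scale data; with groups of roughly
30-35 subjects this demands genuine density while tolerating group-size
imbalance.

## OPTICS, reachability plots, and the separation index

`run_optics()` implements the classical ordering: the *core distance* of a
point is the distance to its `min_pts`-th nearest point, **counting the
point itself** — the same neighborhood convention as DBSCAN, which is what
makes the equivalence below exact (conventions differ across published
implementations, so this is stated explicitly); the *reachability* of $p$
from a processed core point $s$ is $\max(\text{core}(s), d(s, p))$. Points
are processed smallest-current-reachability first, ties to the lowest
index, so the ordering is deterministic. The generating distance defaults
to the maximum pairwise distance — always "large enough"; enlarging it
further cannot change the result. The first point of the ordering (and of
every connected component) has undefined reachability, stored as `Inf` and
serialized as `inf`.

**Extraction.** `extract_clusters()` scans the ordering with a threshold
$t$: reachability above $t$ ends the current cluster, and the point starts
a new cluster if its own core distance is within $t$, otherwise it is an
outlier. On core points this reproduces the DBSCAN partition at
$\varepsilon = t$ (a property the test suite checks on random instances).
The default threshold (`auto_threshold()`) is the midpoint of the largest
gap in the sorted defined reachability values, which splits them into a
valley (within-cluster) and a peak (between-cluster) population.
Steepness-based extraction variants are deliberately out of scope; the
threshold rule is the only one with a testable DBSCAN-equivalence property.

**Separation index.** For cluster $k$ bounded in the ordering by peaks at
positions $i$ and $j$,

$$S_k = \frac{\tfrac12\,(RP(i) + RP(j))}
             {\tfrac1{j-i-1}\sum_{m=i+1}^{j-1} RP(m)},$$

with $RP$ the reachability value; the final index is the mean over
clusters (`separation_index()`). Peaks are the reachability values at
cluster-*start* boundary points (the point opening cluster $k$ and the
point opening cluster $k+1$) — a deterministic convention; local-maxima
peak hunting is not attempted. The first and last points of the plot are
left out: an undefined bounding peak (the `Inf` that opens the plot, or a
missing right boundary after the last cluster) is replaced by the nearest
defined bounding peak, and the last plot position never enters a valley.
Clusters whose valley is empty are skipped with a warning. The index is
scale-invariant (a ratio) and grows as valleys deepen relative to peaks —
higher means more cleanly separated clusters.

## R-CLAN: robustness as a terminating SNR

`r_clan()` measures how much additive white Gaussian noise a clustering
configuration tolerates before its result changes. Signal power $S$ is the
mean squared feature value; for a target SNR (dB) the noise variance is
$N = S / 10^{\mathrm{SNR}/10}$. Starting at 100 dB (practically clean) the
ladder descends 1 dB per rung; at each rung the **original** matrix is
corrupted afresh at the rung's SNR, clustered, and scored for overall
purity. The ladder stops at the first rung whose purity differs from the
baseline purity at the top rung — that SNR is the *terminating SNR*; lower
values mean the structure survived more noise, i.e. more robustness. A
floor of 0 dB censors configurations whose purity never changes.

Design choices, each switchable:

* *Fresh corruption per rung* (not cumulative): only fresh corruption makes
  the per-rung SNR exact. A cumulative interpretation can be emulated by
  the caller but is not the default.
* *Parameters frozen from clean data*: the DBSCAN radius and OPTICS
  threshold are selected once on the clean matrix and reused at every rung
  (`clusterer_dbscan()`, `clusterer_optics()`), isolating the noise
  sensitivity of the clustering itself; `clusterer_dbscan_auto()` /
  `clusterer_optics_auto()` re-select per rung instead.
* *One noise draw per rung* by default; `replicates_per_snr` enables a
  majority-vote purity across draws to reduce draw-to-draw variance.
* "Structure changed" is operationalized exactly as *the overall purity
  value changed from baseline*, not as any relabeling.
* A clusterer failure at a rung terminates the ladder (with a warning) —
  a collapse is a structure change.

## Purity against diagnostic labels

`purity()` matches clusters to groups one-to-one by maximizing total
agreement on the contingency table (exhaustive optimal assignment, exact
up to 8 clusters/groups; a greedy variant exists for sensitivity
analysis). Optimal rather than greedy matching is used because a
group-wise success-rate table presumes a single cluster per diagnostic
group. Outliers stay in the denominator and never count as correct —
success rates are fractions of each group's full size. When cluster and
group counts differ, extra clusters match nothing, missing groups score
0%, and a warning is emitted.

## The synthetic cohort generator

Real cohorts of this design are access-restricted, so the generator
supplies study-shaped data with known ground truth: 132 subjects in four
groups (35/34/34/29: control, early MCI, late MCI, AD), 200 ROIs, 135
retained timepoints, age/gender/motion nuisance covariates drawn from the
emulated cohort's demographics (covariates carry no feature effect unless
`covariate_effect` injects an age confound for testing the adjustment).

**Feature-space cohorts** (`generate_feature_cohort()`) draw each group
from an isotropic Gaussian around centroids either on a simplex
(equidistant, the default) or on a line ("spectrum", intermediate groups
between control and AD). Pairwise centroid separation is
`sfc_effect * within_group_sd`; the default of 16 within-SD units in 100
dimensions is *moderate* — the within-cluster spread between two points is
$\sqrt{2 \cdot 100}\,\sigma \approx 14\sigma$, so clusters nearly touch —
and yields four clusters with purity near 100% under the default selection
rules, degrading quickly below separation ~13.

**Time-series cohorts** (`generate_roi_timeseries()`) give each affected
ROI pair a shared latent signal with sinusoidally modulated mixing:
$y_t = \rho(t)\,x_t + \sqrt{1 - \rho(t)^2}\,e_t$ with white unit-variance
$x, e$ and $\rho(t) = \rho_0 + A \sin(2\pi t / P + \phi)$. With constant
mixing the long-run correlation is exactly $\rho_0$, so the level and the
fluctuation of connectivity are dialled independently: the group level of
$\rho_0$ *declines* across the disease spectrum by `sfc_effect`
(connectivity loss; default 0.45 from a baseline of 0.5) while the
amplitude $A$ *rises* by `dfc_effect` (default 0.3 to 0.85). The
modulation period defaults to 67.5 timepoints — two full cycles in a
135-timepoint scan — so the modulation averages out of the full-scan
correlation; with partial cycles the residual leaks into SFC estimates and
contaminates the static arm. Unaffected ROIs are independent white noise;
affected pairs are disjoint (each ROI in at most one pair), by default
using all ROIs (100 pairs), so a top-100 selection can in principle
recover them all.

**What the generator does and does not emulate.** It reproduces the
*feature-level* structure the analysis consumes: group-dependent
connectivity strength, group-dependent connectivity variability, nuisance
covariates, additive Gaussian noise. It does not simulate scanner physics,
head-motion artifacts, spatial structure, hemodynamics, autocorrelated
BOLD noise, or non-Gaussian (e.g. Rician) noise — so passing tests
demonstrate the *pipeline's* correctness and the method's behavior under
the declared generative model, not performance on real scans. Two
consequences discovered during development and worth knowing:

* The sampling-noise floor of windowed Pearson correlations depends on
  $\rho^2$, so groups that differ in $|\rho_0|$ differ slightly in DFC
  variance even when their modulation amplitudes match. The generator does
  not hide this; tests of "no dynamic effect" use mirrored levels
  ($\rho_0 = \pm c$) where the floors genuinely coincide.
* With 135 timepoints and 30-timepoint windows a variance-of-windowed-
  correlation estimate rests on only a handful of effectively independent
  windows. Group *means* separate cleanly (feature selection recovers the
  affected pairs essentially perfectly), but *individual-level* density
  clustering on DFC-variance features remains partially merged at
  plausible amplitudes — the intermediate groups fuse first. This mirrors
  the general experience that intermediate disease stages are the hardest
  to resolve, and it is a genuine small-sample property, not a bug.

## Problem sizes used in the shipped checks

The test suite runs the clustering oracles on hundreds of random
two-dimensional instances ($n \le 40$), the cohort-level checks on
132-subject feature cohorts (20 seeds), the R-CLAN orderings on 20-seed
ladders from 60 dB, and the feature-recovery checks on full 132 x 200 x 135
time-series cohorts (10 seeds, fixed 30-timepoint window). The
`scripts/acceptance.R` analysis runs one full time-series cohort per seed
end to end, including four R-CLAN ladders from 100 dB.

## Known limitations

* Distances are Euclidean; no alternative metrics are wired in (the
  `dist_matrix()` internals centralize the choice).
* The epsilon plot evaluates a finite grid (200 radii by default), so the
  chosen radius is resolved to one grid spacing; refinement changes it by
  at most that much.
* Exhaustive cluster-group matching is exact only up to 8 entities per
  side; beyond that a greedy fallback (with warning) is used.
* The ADF critical values are tabulated at conventional levels; arbitrary
  test levels are not supported.
* OPTICS extraction is threshold-based only; steepness-based extraction is
  out of scope.
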