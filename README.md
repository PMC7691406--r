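# fcclust

Unsupervised stratification of subjects from resting-state fMRI
functional-connectivity features, for researchers who want to know whether
diagnostic structure (e.g. stages of cognitive impairment alongside healthy
controls) is *inherent* in brain-connectivity data rather than imposed by a
supervised classifier. The package clusters subjects with density-based
algorithms — which need no preset cluster count and detect outliers — and
only afterwards compares the clusters against the known diagnoses.

## What it computes

**Features.** For every pair of regions of interest (ROIs) and every
subject:

* *static functional connectivity* (SFC): the Pearson correlation
  r(x, y) of the two ROI time series over the whole scan;
* *dynamic functional connectivity variance* (DFC variance): the sample
  variance over time of sliding-window Pearson correlations, with the
  window length chosen adaptively as the shortest length whose windows
  pass an augmented Dickey-Fuller stationarity screen.

Each feature family is reduced to the top-k features (default k = 100) by
the p-value of a covariate-adjusted group F-test
(`feature ~ group + age + gender + motion`).

**Clustering.** From-scratch DBSCAN and OPTICS (Euclidean metric). The
DBSCAN radius is selected by the *epsilon plot*: DBSCAN is run over a grid
of radii in (0, 2·eps_init] (eps_init from the k-distance-graph elbow), and
the midpoint of the widest radius range with a constant multi-cluster count
is chosen. OPTICS clusters are extracted from the reachability plot with a
threshold placed in the largest gap of the reachability values; cluster
distinctness is summarized by the *separation index*

    S_k = mean(bounding peak heights) / mean(valley reachability values),

averaged over clusters (higher = cleaner separation).

**Evaluation and robustness.** *Cluster purity* is the percentage of
subjects whose cluster maps to their true group under an optimal one-to-one
cluster-group matching (outliers count as errors). *R-CLAN* (recursive
clustering using additive noise) corrupts the features with white Gaussian
noise at SNR = 100 dB, 99 dB, ... (`SNR = 10 log10(S/N)`, S = mean squared
feature value) and reports the first SNR at which purity changes — the
*terminating SNR*; lower means more robust.

Because the cohorts this design targets are access-restricted, the package
ships a synthetic generator (`generate_feature_cohort()`,
`generate_roi_timeseries()`) that emulates the study shape: 132 subjects in
four groups (35 control / 34 EMCI / 34 LMCI / 29 AD), 200 ROIs, 135
timepoints, group-dependent connectivity strength and variability, nuisance
covariates, reproducible under a seed.

## Worked example

```r
library(fcclust)

cfg <- cohort_config(seed = 42)          # 132 subjects, 4 groups, 100 features
cohort <- generate_feature_cohort(cfg)

db <- dbscan_auto(cohort$features)       # epsilon-plot radius selection
db$epsplot
#> <fc_epsplot> 200 radii in (0, 29.18]; chosen eps = 15.1 (step with 4 clusters over [12.84, 17.36])
purity(db$clustering, cohort$labels)
#> <fc_purity> overall 100.00%, 0 outlier(s)
#>   control  100.00%
#>   EMCI     100.00%
#>   LMCI     100.00%
#>   AD       100.00%

op <- optics_auto(cohort$features)       # reachability-threshold extraction
separation_index(op$profile, op$clustering)
#> <fc_separation> mean index 1.3255 over 4 cluster(s)

rc <- r_clan(cohort$features, cohort$labels,
             clusterer_dbscan(db$epsplot$chosen_eps, min_pts = 10),
             rclan_config(seed = 42))
rc
#> <fc_rclan> terminating SNR 12 dB (baseline purity 100.00%)
```

Reading the output: the epsilon plot found that a 4-cluster solution is
stable over the widest radius range ([12.84, 17.36]) and fixed the radius
at its midpoint; both density methods recover the four generating groups
perfectly on this cohort; and the DBSCAN configuration keeps that perfect
purity down to 13 dB of additive noise, first changing at 12 dB.

A full time-series analysis (simulate ROI series → SFC/DFC features →
cluster → purity/robustness) is wrapped in `run_pipeline(from =
"timeseries")`; a thin command-line interface over the same functions is
installed at `inst/cli/fcclust` (subcommands `simulate`, `features`,
`cluster-dbscan`, `cluster-optics`, `rclan`, `report`).

## Documentation

The methods vignette (`vignettes/fcclust-methods.Rmd`) documents the
models and their assumptions, every tunable parameter with its default and
rationale, the deterministic tie-breaks and degenerate-input rules, what
the synthetic generator does and does not emulate, and known limitations.
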