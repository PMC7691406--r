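Package: fcclust
Title: Density-Based Clustering of Static and Dynamic Functional
    Connectivity Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised stratification of subjects from resting-state
    functional-connectivity features. Computes static functional
    connectivity (Pearson correlation between region-of-interest time
    series) and the variance of sliding-window dynamic connectivity with
    an adaptive, stationarity-based window length, ranks features by
    covariate-adjusted group F-tests, and clusters subjects with
    from-scratch DBSCAN and OPTICS implementations. Includes the
    epsilon-plot rule for choosing the DBSCAN radius, reachability-plot
    cluster extraction with a separation index summarizing cluster
    distinctness, a recursive additive-noise protocol (R-CLAN) that
    measures robustness as the signal-to-noise ratio at which cluster
    purity first changes, and a synthetic cohort generator emulating a
    four-group cognitive-impairment study for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
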