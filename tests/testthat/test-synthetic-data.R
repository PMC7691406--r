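test_that("configuration validation rejects bad inputs", {
  expect_error(cohort_config(group_sizes = c(10, 0)), "positive")
  expect_error(cohort_config(n_timepoints = 1), ">= 2")
  expect_error(cohort_config(within_group_sd = 0), "within_group_sd")
  expect_error(cohort_config(sfc_effect = -1), "sfc_effect")
  expect_error(cohort_config(n_rois = 10, n_affected_pairs = 6), "disjoint")
})

test_that("feature cohort has the default 132 x 100 shape and group labels", {
  co <- generate_feature_cohort(cohort_config(seed = 11))
  expect_equal(dim(co$features$values), c(132L, 100L))
  expect_equal(as.vector(table(co$labels$group)), c(35L, 34L, 34L, 29L))
  expect_equal(levels(co$labels$group), c("control", "EMCI", "LMCI", "AD"))
  expect_equal(nrow(co$labels), 132L)
})

test_that("identical config and seed give bit-identical cohorts", {
  cfg <- cohort_config(seed = 5)
  a <- generate_feature_cohort(cfg)
  b <- generate_feature_cohort(cfg)
  expect_identical(a, b)
  cfg2 <- cohort_config(group_sizes = c(8, 8), n_rois = 10, n_timepoints = 40,
                        seed = 5)
  t1 <- generate_roi_timeseries(cfg2)
  t2 <- generate_roi_timeseries(cfg2)
  expect_identical(t1, t2)
})

test_that("zero effect leaves group centroids statistically coincident", {
  # permutation test on the max inter-centroid distance, n = 500 subjects
  cfg <- cohort_config(group_sizes = c(125, 125, 125, 125), n_features = 30,
                       sfc_effect = 0, seed = 7)
  co <- generate_feature_cohort(cfg)
  x <- co$features$values
  g <- co$labels$group
  stat <- function(gg) {
    cen <- apply(x, 2, function(col) tapply(col, gg, mean))
    max(dist(cen))
  }
  obs <- stat(g)
  set.seed(99)
  null <- replicate(500, stat(sample(g)))
  expect_gt(mean(null >= obs), 0.01)  # observed not extreme under the null
})

test_that("vanishing dispersion with positive effect gives perfectly pure clusters", {
  # centroid separation is sfc_effect * within_group_sd, so scale eps between
  # the vanishing within-group spread and the (tiny) centroid separation
  cfg <- cohort_config(group_sizes = c(10, 10, 10, 10), n_features = 20,
                       sfc_effect = 1e3, within_group_sd = 1e-6, seed = 3)
  co <- generate_feature_cohort(cfg)
  cl <- run_dbscan(co$features, eps = 1e-4, min_pts = 5)
  expect_equal(cl$n_clusters, 4L)
  expect_equal(purity(cl, co$labels)$overall_purity, 100)
})

test_that("median inter-centroid distance is non-decreasing in the effect size", {
  med_dist <- function(eff, seed) {
    cfg <- cohort_config(group_sizes = c(15, 15, 15, 15), n_features = 25,
                         sfc_effect = eff, seed = seed)
    co <- generate_feature_cohort(cfg)
    cen <- apply(co$features$values, 2, function(col) tapply(col, co$labels$group, mean))
    stats::median(dist(cen))
  }
  for (seed in 1:10) {
    d <- vapply(c(0, 4, 8, 16), med_dist, numeric(1), seed = seed)
    expect_true(all(diff(d) >= 0))
  }
})

test_that("ROI time-series cohorts have the declared shape", {
  cfg <- cohort_config(group_sizes = c(3, 3), n_rois = 8, n_timepoints = 50,
                       seed = 2)
  co <- generate_roi_timeseries(cfg)
  expect_equal(dim(co$timeseries$data), c(6L, 8L, 50L))
  expect_true(all(is.finite(co$timeseries$data)))
  # default-config shape (subjects x ROIs x timepoints = 132 x 200 x 135)
  # is asserted indirectly: the config defaults encode it
  cfg_def <- cohort_config()
  expect_equal(c(sum(cfg_def$group_sizes), cfg_def$n_rois, cfg_def$n_timepoints),
               c(132L, 200L, 135L))
})

test_that("constant mixing weight yields the closed-form static correlation", {
  # y_t = rho * x_t + sqrt(1 - rho^2) e_t with unit-variance x, e
  # => cor(x, y) -> rho as T grows; +/- 0.05 at T = 5000
  cfg <- cohort_config(group_sizes = c(2, 2), n_rois = 4, n_timepoints = 5000,
                       rho_base = 0.5, sfc_effect = 0.4, dfc_effect = 0,
                       dfc_base = 0, seed = 3)
  co <- generate_roi_timeseries(cfg)
  lev <- (as.integer(co$labels$group) - 1L)  # 0 or 1
  expected <- 0.5 - 0.4 * lev
  for (s in 1:4) {
    emp <- cor(co$timeseries$data[s, 1, ], co$timeseries$data[s, 2, ])
    expect_lt(abs(emp - expected[s]), 0.05)
  }
})

test_that("static effect without dynamic effect moves SFC but not DFC variance", {
  # two-group cohort, 100 subjects per group, alpha = 0.01; rho0 = +/- 0.35
  # so the windowed-correlation sampling floor (which depends on rho^2)
  # matches across groups and any DFC-variance difference would be spurious
  cfg <- cohort_config(group_sizes = c(100, 100), n_rois = 6,
                       n_timepoints = 135, sfc_effect = 0.7, dfc_effect = 0,
                       dfc_base = 0.15, rho_base = 0.35, n_affected_pairs = 2,
                       seed = 21)
  co <- generate_roi_timeseries(cfg)
  g <- co$labels$group
  sfc <- vapply(seq_len(200), function(s)
    cor(co$timeseries$data[s, 1, ], co$timeseries$data[s, 2, ]), numeric(1))
  dfcv <- vapply(seq_len(200), function(s) {
    r <- sliding_window_corr(co$timeseries$data[s, 1, ],
                             co$timeseries$data[s, 2, ], w = 30)
    dfc_variance(r)
  }, numeric(1))
  expect_lt(t.test(sfc ~ g)$p.value, 0.01)   # static correlation differs
  expect_gt(t.test(dfcv ~ g)$p.value, 0.01)  # window variance does not
})

test_that("top-ranked features concentrate on affected pairs across seeds", {
  hits <- vapply(1:10, function(seed) {
    cfg <- cohort_config(group_sizes = c(12, 12, 12, 12), n_rois = 20,
                         n_timepoints = 120, n_affected_pairs = 5,
                         sfc_effect = 0.6, dfc_effect = 0, dfc_base = 0,
                         rho_base = 0.75, seed = seed)
    co <- generate_roi_timeseries(cfg)
    sfc <- static_fc(co$timeseries)
    pairs <- which(upper.tri(sfc[, , 1]), arr.ind = TRUE)
    pairs <- pairs[order(pairs[, 1], pairs[, 2]), ]
    v <- t(apply(sfc, 3, function(m) m[pairs]))
    colnames(v) <- paste(pairs[, 1], pairs[, 2], sep = "-")
    sel <- select_top_features(fc_features(v), co$labels, k = 5)
    aff <- paste(co$timeseries$affected_pairs$roi_a,
                 co$timeseries$affected_pairs$roi_b, sep = "-")
    mean(colnames(sel$features$values) %in% aff)
  }, numeric(1))
  expect_gte(mean(hits == 1), 0.9)
})
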