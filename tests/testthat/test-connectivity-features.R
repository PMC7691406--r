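test_that("static correlation matches hand-computed Pearson values", {
  x <- c(1, 2, 3, 4)
  expect_equal(cor(x, x), 1)
  m <- cbind(a = x, b = c(1, 2, 4, 3))
  r <- static_fc(m)
  expect_equal(r["a", "b"], 0.8)           # hand: 4 / sqrt(5 * 5)
  expect_equal(static_fc(cbind(x, -x))[1, 2], -1)
  expect_true(isSymmetric(r))
  expect_equal(diag(r), c(a = 1, b = 1))
})

test_that("zero-variance series are rejected with the ROI named", {
  m <- cbind(good = rnorm(10), flat = rep(2, 10))
  expect_error(static_fc(m), "flat")
})

test_that("cohort-level static FC is symmetric with unit diagonal per subject", {
  cfg <- cohort_config(group_sizes = c(3, 3), n_rois = 7, n_timepoints = 40,
                       seed = 4)
  co <- generate_roi_timeseries(cfg)
  arr <- static_fc(co$timeseries)
  expect_equal(dim(arr), c(7L, 7L, 6L))
  for (s in 1:6) {
    expect_true(isSymmetric(arr[, , s]))
    expect_equal(diag(arr[, , s]), setNames(rep(1, 7), co$timeseries$roi_ids))
    expect_true(all(abs(arr[, , s]) <= 1))
  }
})

test_that("sliding-window correlation matches hand-computed windows", {
  x <- c(1, 2, 3, 4)
  y <- c(1, 2, 4, 3)
  r <- sliding_window_corr(x, y, w = 3)
  # window 1: cor((1,2,3), (1,2,4)) = 3 / sqrt(2 * 14/3) = sqrt(27/28)
  expect_equal(r, c(sqrt(27 / 28), 0.5), tolerance = 1e-12)
  # identical series: all windows at 1
  expect_equal(sliding_window_corr(x, x, w = 2), rep(1, 3))
  # single-window limit equals the static correlation
  expect_equal(sliding_window_corr(x, y, w = 4), cor(x, y))
})

test_that("sliding windows flag zero-variance segments and shrink with w", {
  x <- c(1, 1, 1, 2, 3, 4)
  y <- c(2, 1, 3, 1, 2, 5)
  expect_warning(r <- sliding_window_corr(x, y, w = 3), "zero variance")
  expect_true(is.na(r[1]))
  # output length strictly decreases as w increases
  lens <- vapply(2:5, function(w)
    length(suppressWarnings(sliding_window_corr(x, y, w))), integer(1))
  expect_true(all(diff(lens) < 0))
})

test_that("dfc_variance is the sample variance of valid entries", {
  expect_equal(dfc_variance(c(1, 1, 1)), 0)
  expect_equal(dfc_variance(c(0.5, -0.5)), 0.5)     # divisor n - 1
  s <- c(0.2, -0.1, 0.4, 0.05)
  expect_equal(dfc_variance(s + 0.3), dfc_variance(s))  # shift invariance
  expect_equal(dfc_variance(c(0.1, NA, 0.3)), var(c(0.1, 0.3)))
  expect_error(dfc_variance(c(0.5, NA)), "valid")
})

test_that("vectorized pair correlations agree with the single-pair routine", {
  set.seed(8)
  x <- matrix(rnorm(40 * 5), 40, 5)
  pairs <- fcclust:::upper_pairs(5)
  rmat <- fcclust:::sliding_corr_pairs(x, w = 12, pairs)
  for (j in sample(nrow(pairs), 4)) {
    expect_equal(rmat[, j],
                 sliding_window_corr(x[, pairs[j, 1]], x[, pairs[j, 2]], 12),
                 tolerance = 1e-10)
  }
})

test_that("ADF-based window length finds white noise stationary at the floor", {
  spec <- window_spec(adf_stride = 5)
  got <- vapply(1:100, function(seed) {
    set.seed(seed)
    w <- adf_window_length(rnorm(135), spec)
    as.integer(w)
  }, integer(1))
  expect_gte(mean(got == spec$min_len), 0.95)
})

test_that("random walks are flagged non-stationary at the ceiling", {
  spec <- window_spec(adf_stride = 5)
  res <- vapply(1:100, function(seed) {
    set.seed(seed)
    w <- adf_window_length(cumsum(rnorm(135)), spec)
    c(as.integer(w), attr(w, "nonstationary"))
  }, numeric(2))
  expect_gte(mean(res[1, ] == spec$max_len & res[2, ] == 1), 0.90)
})

test_that("degenerate and invalid window-length inputs are handled", {
  spec <- window_spec()
  w <- adf_window_length(rep(3, 135), spec)
  expect_equal(as.integer(w), spec$max_len)
  expect_true(attr(w, "nonstationary"))
  expect_error(adf_window_length(rnorm(25), spec), "min_len")
  expect_error(adf_window_length(rnorm(50), window_spec(max_len = 80)),
               "max_len")
})

test_that("covariate-adjusted selection ranks group effects above covariate effects", {
  # feature 1 = pure age effect, feature 2 = group shift, rest noise
  wins <- vapply(1:100, function(seed) {
    set.seed(seed)
    g <- factor(rep(c("a", "b"), each = 20))
    age <- rnorm(40, 70, 5)
    y <- matrix(rnorm(40 * 10), 40, 10)
    y[, 1] <- 2 * age + rnorm(40)
    y[, 2] <- y[, 2] + 1.5 * (as.integer(g) - 1)
    labels <- data.frame(subject = sprintf("s%02d", 1:40), group = g,
                         age = age, gender = rep_len(0:1, 40),
                         motion = rnorm(40))
    sel <- select_top_features(fc_features(y), labels, k = 10)
    sel$stats$rank[2] < sel$stats$rank[1]
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("null features give uniform covariate-adjusted p-values", {
  set.seed(123)
  n <- 132
  g <- factor(rep(c("a", "b", "c", "d"), c(35, 34, 34, 29)))
  labels <- data.frame(subject = sprintf("s%03d", 1:n), group = g,
                       age = rnorm(n, 72, 6), gender = rbinom(n, 1, 0.5),
                       motion = rnorm(n))
  y <- matrix(rnorm(n * 2000), n, 2000)
  sel <- select_top_features(fc_features(y), labels, k = 100)
  ks <- ks.test(sel$stats$p, "punif")
  expect_gt(ks$p.value, 0.01)
  expect_equal(ncol(sel$features$values), 100L)
  expect_equal(sel$stats$p[order(sel$stats$rank)][1:100],
               sort(sel$stats$p)[1:100])
})

test_that("selection is deterministic and breaks p-value ties by feature index", {
  set.seed(5)
  y <- matrix(rnorm(30 * 8), 30, 8)
  y <- cbind(y, y[, 1])  # duplicated feature -> exactly tied p-values
  colnames(y) <- paste0("F", 1:9)
  labels <- labels_for(rep(c("a", "b"), each = 15))
  labels$age <- rnorm(30)
  s1 <- select_top_features(fc_features(y), labels, k = 9)
  s2 <- select_top_features(fc_features(y), labels, k = 9)
  expect_identical(s1, s2)
  r1 <- s1$stats$rank[1]
  r9 <- s1$stats$rank[9]
  expect_lt(r1, r9)  # earlier index wins the tie
})

test_that("rank-deficient covariate designs are rejected with names", {
  y <- matrix(rnorm(20 * 3), 20, 3)
  labels <- labels_for(rep(c("a", "b"), each = 10))
  labels$motion <- labels$age  # collinear
  expect_error(select_top_features(fc_features(y), labels, k = 2),
               "collinear")
})

test_that("build_feature_matrices returns k columns per family and sane values", {
  cfg <- cohort_config(group_sizes = c(6, 6, 6, 6), n_rois = 12,
                       n_timepoints = 70, n_affected_pairs = 4, seed = 9)
  co <- generate_roi_timeseries(cfg)
  fb <- build_feature_matrices(co$timeseries, co$labels, k = 10,
                               spec = window_spec(max_len = 50, adf_stride = 5,
                                                  n_series = 10))
  expect_equal(dim(fb$sfc$features$values), c(24L, 10L))
  expect_equal(dim(fb$dfc$features$values), c(24L, 10L))
  expect_true(all(fb$dfc$features$values >= 0 & fb$dfc$features$values <= 1))
  expect_true(all(abs(fb$sfc$features$values) <= 1))
  expect_equal(unique(fb$sfc$features$feature_info$measure), "SFC")
  expect_equal(unique(fb$dfc$features$feature_info$measure), "DFCvar")
  # 3 ROIs -> 3 candidate pairs per measure
  expect_equal(nrow(fcclust:::upper_pairs(3)), 3L)
})
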