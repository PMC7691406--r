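test_that("core distances follow the neighbor-counting convention", {
  # 5 equally spaced collinear points, spacing s: with min_pts = 2 the
  # second-nearest point (self counted first) of an interior point is at
  # distance s; endpoints likewise reach a neighbor at s
  s <- 0.7
  x <- matrix(s * (0:4), ncol = 1)
  pr <- run_optics(x, min_pts = 2)
  cd <- pr$core_dist[order(pr$ordering)]
  expect_equal(cd, rep(s, 5))
  # min_pts = 3: interior points reach their 2nd other neighbor at s,
  # endpoints at 2s
  pr3 <- run_optics(x, min_pts = 3)
  cd3 <- pr3$core_dist[order(pr3$ordering)]
  expect_equal(cd3, c(2 * s, s, s, s, 2 * s))
})

test_that("coincident points give zero core and reach; first point undefined", {
  x <- matrix(0, 8, 2)
  pr <- run_optics(x, min_pts = 3)
  expect_true(is.infinite(pr$reach[1]))
  expect_equal(pr$reach[-1], rep(0, 7))
  expect_equal(pr$core_dist, rep(0, 8))
  expect_true(setequal(pr$ordering, 1:8))
})

test_that("threshold extraction recovers well-separated blobs", {
  b <- make_blobs(rbind(c(0, 0), c(10, 0)), n_per = 15, sd = 0.5, seed = 2)
  pr <- run_optics(b$x, min_pts = 4)
  cl <- extract_clusters(pr, threshold = 3)
  expect_equal(cl$n_clusters, 2L)
  expect_true(same_partition(cl$assignment, b$truth))
  # cross-check against DBSCAN at eps = threshold on core points
  db <- run_dbscan(b$x, eps = 3, min_pts = 4)
  core <- brute_dbscan(b$x, 3, 4)$core
  expect_true(same_partition(cl$assignment[core], db$assignment[core]))
})

test_that("threshold extremes behave as documented", {
  b <- make_blobs(rbind(c(0, 0), c(6, 0)), n_per = 10, sd = 0.4, seed = 5)
  pr <- run_optics(b$x, min_pts = 3)
  hi <- extract_clusters(pr, threshold = max(pr$reach[is.finite(pr$reach)]) + 1)
  expect_equal(hi$n_clusters, 1L)
  # every point with a defined core distance joins the single cluster
  expect_equal(sum(hi$assignment > 0), sum(is.finite(pr$core_dist)))
  lo <- extract_clusters(pr, threshold = 1e-9)
  expect_equal(sum(lo$assignment > 0), 0L)  # nothing dense at that scale
})

test_that("extraction at t partitions core points like DBSCAN at eps = t", {
  set.seed(77)
  for (i in 1:25) {
    n <- sample(10:40, 1)
    x <- matrix(runif(n * 2, 0, 4), n, 2)
    min_pts <- sample(2:5, 1)
    t <- runif(1, 0.2, 1.5)
    pr <- run_optics(x, min_pts = min_pts)
    oc <- extract_clusters(pr, t)
    db <- run_dbscan(x, eps = t, min_pts = min_pts)
    core <- brute_dbscan(x, t, min_pts)$core
    expect_true(same_partition(oc$assignment[core], db$assignment[core]))
  }
})

test_that("enlarging the generating distance does not change extracted clusters", {
  b <- make_blobs(rbind(c(0, 0), c(8, 0), c(4, 7)), n_per = 10, sd = 0.5,
                  seed = 11)
  d_max <- max(dist(b$x))
  pr1 <- run_optics(b$x, min_pts = 4, eps = d_max)
  pr2 <- run_optics(b$x, min_pts = 4, eps = 10 * d_max)
  c1 <- extract_clusters(pr1, 2.5)
  c2 <- extract_clusters(pr2, 2.5)
  expect_identical(c1$assignment, c2$assignment)
})

test_that("auto threshold lands in the largest reachability gap", {
  reach <- c(Inf, rep(0.1, 8), 5.0, rep(0.12, 9), 4.8, rep(0.09, 7))
  pr <- manual_profile(reach)
  # sorted defined values jump from 0.12 to 4.8 -> midpoint 2.46
  expect_equal(auto_threshold(pr), 2.46)
  pr_scaled <- manual_profile(c(Inf, reach[-1] * 3))
  expect_equal(auto_threshold(pr_scaled), 3 * 2.46)
  expect_error(auto_threshold(manual_profile(c(Inf, rep(1, 5)))), "equal")
})

test_that("separation index reproduces the hand-worked example", {
  # cluster bounded by peaks 3 and 5 with valley (2, 2): S = (0.5*(3+5))/2 = 2
  reach <- c(Inf, 0.5, 3, 2, 2, 5, 0.7, 0.8, 0.6)
  pr <- manual_profile(reach)
  cl <- extract_clusters(pr, threshold = 2.5)
  si <- separation_index(pr, cl)
  expect_equal(si$per_cluster$s_k[si$per_cluster$cluster == 2], 2.0)
  expect_equal(si$mean_index, mean(si$per_cluster$s_k))
})

test_that("flat reachability gives separation index 1", {
  reach <- c(Inf, rep(2, 8))
  pr <- manual_profile(reach)
  cl <- fc_clustering(c(1, 1, 1, 2, 2, 2, 3, 3, 3))
  si <- separation_index(pr, cl)
  expect_equal(si$per_cluster$s_k, rep(1, nrow(si$per_cluster)))
  expect_equal(si$mean_index, 1)
})

test_that("separation index is scale-invariant and valley-monotone", {
  reach <- c(Inf, 0.5, 3, 2, 2, 5, 0.7, 0.8, 0.6)
  pr <- manual_profile(reach)
  cl <- extract_clusters(pr, threshold = 2.5)
  s0 <- separation_index(pr, cl)
  for (c_mult in c(0.5, 2, 10)) {
    prc <- manual_profile(reach * c_mult)
    clc <- extract_clusters(prc, threshold = 2.5 * c_mult)
    sc <- separation_index(prc, clc)
    expect_equal(sc$per_cluster$s_k, s0$per_cluster$s_k, tolerance = 1e-12)
  }
  # shrinking valley values (peaks fixed) strictly increases every S_k
  reach_deep <- reach
  reach_deep[c(4, 5)] <- reach[c(4, 5)] * 0.5
  sd2 <- separation_index(pr, cl)
  sdeep <- separation_index(manual_profile(reach_deep), cl)
  expect_true(all(sdeep$per_cluster$s_k >= sd2$per_cluster$s_k))
  expect_gt(sdeep$per_cluster$s_k[2], sd2$per_cluster$s_k[2])
})

test_that("ordering determinism: equal-reachability ties go to the lowest index", {
  x <- matrix(c(0, 0.5, 1, 1.5, 2), ncol = 1)  # symmetric spacing
  pr1 <- run_optics(x, min_pts = 2)
  pr2 <- run_optics(x, min_pts = 2)
  expect_identical(pr1$ordering, pr2$ordering)
  expect_equal(pr1$ordering[1], 1L)  # first unprocessed = lowest index
})
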