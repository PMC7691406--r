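# From-scratch DBSCAN with k-distance initialization and epsilon-plot
# radius selection.

#' Density-clustering result container
#'
#' @param assignment Integer vector: cluster label per point (1..K in
#'   discovery order), 0 for outliers/noise.
#' @param params List of the parameters that produced the assignment.
#' @return Object of class `fc_clustering` with elements `assignment`,
#'   `n_clusters`, `params`.
#' @export
fc_clustering <- function(assignment, params = list()) {
  assignment <- as.integer(assignment)
  stopifnot(all(assignment >= 0L))
  pos <- unique(assignment[assignment > 0L])
  if (length(pos) && !identical(sort(pos), seq_along(pos))) {
    stop("cluster labels must be contiguous 1..K", call. = FALSE)
  }
  structure(list(assignment = assignment, n_clusters = length(pos),
                 params = params),
            class = "fc_clustering")
}

#' @export
print.fc_clustering <- function(x, ...) {
  cat(sprintf("<fc_clustering> %d points, %d cluster(s), %d outlier(s)\n",
              length(x$assignment), x$n_clusters, sum(x$assignment == 0L)))
  invisible(x)
}

# Full Euclidean distance matrix (cohort sizes make O(n^2) trivial).
dist_matrix <- function(x) {
  as.matrix(stats::dist(feature_values(x)))
}

#' DBSCAN clustering
#'
#' Classical density-based spatial clustering: a point is a *core point* if
#' its eps-neighborhood (points within radius `eps`, the point itself
#' included) holds at least `min_pts` points; clusters are the
#' density-connected components of core points, border points attach to the
#' first cluster whose core point reaches them in scan order (row order),
#' and the remaining points are outliers (label 0). Clusters are numbered
#' 1..K in discovery order.
#'
#' @param x Numeric matrix (points x dimensions) or [fc_features].
#' @param eps Neighborhood radius (> 0), Euclidean metric.
#' @param min_pts Minimum neighborhood size for a core point (>= 1).
#' @param d Optional precomputed distance matrix (reused across radii by
#'   [epsilon_plot_select()]).
#' @return An [fc_clustering] object.
#' @export
run_dbscan <- function(x, eps, min_pts, d = NULL) {
  if (is.null(d)) d <- dist_matrix(x)
  stopifnot(nrow(d) >= 1L, eps > 0, is.finite(eps), min_pts >= 1L)
  nbr <- lapply(seq_len(nrow(d)), function(i) which(d[i, ] <= eps))
  dbscan_core(nbr, min_pts, params = list(method = "dbscan", eps = eps,
                                          min_pts = as.integer(min_pts)))
}

# Core DBSCAN scan over precomputed eps-neighborhood lists (self included).
dbscan_core <- function(nbr, min_pts, params = list()) {
  n <- length(nbr)
  core <- lengths(nbr) >= min_pts
  labels <- rep(NA_integer_, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!is.na(labels[i]) || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- nbr[[i]]
    qpos <- 1L
    while (qpos <= length(queue)) {
      j <- queue[qpos]
      qpos <- qpos + 1L
      if (is.na(labels[j]) || labels[j] == 0L) {
        unvisited <- is.na(labels[j])
        labels[j] <- cl
        if (unvisited && core[j]) queue <- c(queue, nbr[[j]])
      }
    }
  }
  labels[is.na(labels)] <- 0L
  fc_clustering(labels, params = params)
}

#' k-distance graph
#'
#' Distance from every point to its `k`-th nearest neighbor (the point
#' itself excluded), sorted in descending order -- the curve whose elbow
#' initializes the DBSCAN radius search.
#'
#' @param x Points matrix or [fc_features].
#' @param k Neighbor rank (`k < n`).
#' @return Descending numeric vector of length `n`.
#' @export
k_distance_graph <- function(x, k) {
  d <- dist_matrix(x)
  n <- nrow(d)
  if (k >= n) stop("`k` must be smaller than the number of points", call. = FALSE)
  kd <- vapply(seq_len(n), function(i) sort(d[i, -i])[k], numeric(1))
  sort(kd, decreasing = TRUE)
}

#' Elbow of the k-distance graph
#'
#' Deterministic elbow rule: the point of maximum perpendicular distance
#' from the chord joining the first and last points of the descending
#' k-distance curve (kneedle-style). When every point is equidistant from
#' the chord (a straight line), the middle point is returned.
#'
#' @param kdist Descending numeric vector (length >= 3) from
#'   [k_distance_graph()].
#' @return The k-distance value at the elbow (strictly positive when any
#'   distance is positive).
#' @export
initial_eps_estimate <- function(kdist) {
  kdist <- as.numeric(kdist)
  n <- length(kdist)
  if (n < 3L) stop("need at least 3 points", call. = FALSE)
  if (all(kdist == 0)) stop("all k-distances are zero: degenerate data", call. = FALSE)
  xs <- seq_len(n)
  # perpendicular distance from (xs, kdist) to the chord (1, y1)-(n, yn)
  dx <- n - 1
  dy <- kdist[n] - kdist[1L]
  dist_chord <- abs(dy * (xs - 1) - dx * (kdist - kdist[1L])) / sqrt(dx^2 + dy^2)
  mx <- max(dist_chord)
  cand <- which(dist_chord >= mx - 1e-12 * max(mx, 1))
  pick <- cand[ceiling(length(cand) / 2)]
  kdist[pick]
}

#' Epsilon plot and automatic radius selection
#'
#' Runs DBSCAN over a uniform grid of `grid_size` radii in
#' `(0, 2 * eps_init]` and records the cluster count at each radius. The
#' plot is partitioned into maximal constant-count steps; among steps with
#' at least 2 clusters the widest (tie: smaller radius) is selected and its
#' midpoint becomes the chosen radius. If no step reaches 2 clusters the
#' widest 1-cluster step is used with a warning.
#'
#' @param x Points matrix or [fc_features].
#' @param min_pts DBSCAN `min_pts` (default 10 for cohort-scale data).
#' @param eps_init Initial radius estimate; `NULL` computes it from the
#'   elbow of the k-distance graph with `k = min_pts`.
#' @param grid_size Number of grid radii (>= 10; default 200).
#' @return Object of class `fc_epsplot`: `eps_grid`, `n_clusters_at`,
#'   `steps` (data frame: eps_low, eps_high, n_clusters, width),
#'   `chosen_eps`, `chosen_step`, `min_pts`, `eps_init`.
#' @export
epsilon_plot_select <- function(x, min_pts = 10L, eps_init = NULL,
                                grid_size = 200L) {
  d <- dist_matrix(x)
  if (is.null(eps_init)) {
    eps_init <- initial_eps_estimate(k_distance_graph(x, k = min_pts))
  }
  stopifnot(eps_init > 0, grid_size >= 10L)
  grid <- 2 * eps_init * seq_len(grid_size) / grid_size
  # sort each point's neighbor distances once; per-radius neighborhoods are
  # then prefix slices of the sorted lists
  n <- nrow(d)
  ord <- t(apply(d, 1L, order))
  dst <- t(vapply(seq_len(n), function(i) d[i, ord[i, ]], numeric(n)))
  ncl <- vapply(grid, function(e) {
    nbr <- lapply(seq_len(n), function(i) {
      k <- findInterval(e, dst[i, ])
      ord[i, seq_len(k)]
    })
    dbscan_core(nbr, min_pts)$n_clusters
  }, integer(1))
  runs <- rle(ncl)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  steps <- data.frame(
    eps_low = grid[starts],
    eps_high = grid[ends],
    n_clusters = runs$values,
    width = grid[ends] - grid[starts] + grid[1L]  # grid spacing per point
  )
  cand <- which(steps$n_clusters >= 2L)
  if (!length(cand)) {
    warning("no radius produced 2 or more clusters; falling back to the ",
            "widest single-cluster step", call. = FALSE)
    cand <- which(steps$n_clusters == 1L)
    if (!length(cand)) cand <- seq_len(nrow(steps))
  }
  chosen <- cand[which.max(steps$width[cand])]  # ties: first = smaller eps
  chosen_eps <- (steps$eps_low[chosen] + steps$eps_high[chosen]) / 2
  structure(list(eps_grid = grid, n_clusters_at = ncl, steps = steps,
                 chosen_eps = chosen_eps, chosen_step = chosen,
                 min_pts = as.integer(min_pts), eps_init = eps_init),
            class = "fc_epsplot")
}

#' @export
print.fc_epsplot <- function(x, ...) {
  st <- x$steps[x$chosen_step, ]
  cat(sprintf(paste0("<fc_epsplot> %d radii in (0, %.4g]; chosen eps = %.4g ",
                     "(step with %d clusters over [%.4g, %.4g])\n"),
              length(x$eps_grid), max(x$eps_grid), x$chosen_eps,
              st$n_clusters, st$eps_low, st$eps_high))
  invisible(x)
}

#' DBSCAN with automatic radius selection
#'
#' Convenience wrapper: choose the radius with [epsilon_plot_select()] and
#' cluster at that radius.
#'
#' @inheritParams epsilon_plot_select
#' @return List with `clustering` (an [fc_clustering]) and `epsplot`.
#' @export
dbscan_auto <- function(x, min_pts = 10L, grid_size = 200L) {
  ep <- epsilon_plot_select(x, min_pts = min_pts, grid_size = grid_size)
  list(clustering = run_dbscan(x, ep$chosen_eps, min_pts), epsplot = ep)
}
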