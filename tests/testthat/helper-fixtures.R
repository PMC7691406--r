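# Shared fixtures and independent oracles, all built in code.

# Gaussian blobs in d dimensions with given centers (rows) and sd.
make_blobs <- function(centers, n_per, sd = 0.5, seed = 1) {
  set.seed(seed)
  centers <- as.matrix(centers)
  x <- do.call(rbind, lapply(seq_len(nrow(centers)), function(g) {
    matrix(rnorm(n_per * ncol(centers), sd = sd), n_per, ncol(centers)) +
      matrix(centers[g, ], n_per, ncol(centers), byrow = TRUE)
  }))
  list(x = x, truth = rep(seq_len(nrow(centers)), each = n_per))
}

# Brute-force DBSCAN oracle: core set by neighborhood counts (self
# included), clusters as connected components of the core-core adjacency
# at distance <= eps (transitive closure via repeated matrix products),
# border points attached to any reachable component. Independent of the
# package's scan-based implementation.
brute_dbscan <- function(x, eps, min_pts) {
  d <- as.matrix(dist(x))
  n <- nrow(d)
  adj <- d <= eps
  core <- rowSums(adj) >= min_pts
  comp <- rep(0L, n)
  if (any(core)) {
    cc <- adj[core, core, drop = FALSE]
    reach <- cc | diag(TRUE, nrow(cc))
    repeat {
      nxt <- (reach %*% reach) > 0
      if (identical(nxt, reach)) break
      reach <- nxt
    }
    labs <- rep(0L, nrow(cc))
    k <- 0L
    for (i in seq_len(nrow(cc))) {
      if (labs[i] == 0L) {
        k <- k + 1L
        labs[reach[i, ]] <- k
      }
    }
    comp[core] <- labs
  }
  border <- unname(!core & apply(adj[, core, drop = FALSE], 1L, any))
  list(core = unname(which(core)), core_labels = unname(comp[core]),
       is_border = border, assignment = unname(comp))
}

# Same-partition check up to label renaming.
same_partition <- function(a, b) {
  length(a) == length(b) &&
    all(outer(a, a, "==") == outer(b, b, "=="))
}

# Labels data frame for arbitrary cluster-truth vectors (covariates inert).
labels_for <- function(groups, levels = NULL) {
  groups <- as.factor(groups)
  if (!is.null(levels)) groups <- factor(groups, levels = levels)
  data.frame(subject = sprintf("s%03d", seq_along(groups)),
             group = groups,
             age = seq_along(groups) * 0.1 + 70,
             gender = rep_len(c(0L, 1L), length(groups)),
             motion = rep_len(c(-0.3, 0.1, 0.4), length(groups)),
             stringsAsFactors = FALSE)
}

# Hand-built reachability profile (ordering = identity) for index tests.
manual_profile <- function(reach, core_dist = NULL, min_pts = 2L) {
  n <- length(reach)
  if (is.null(core_dist)) core_dist <- rep(0, n)
  structure(list(ordering = seq_len(n), reach = reach, core_dist = core_dist,
                 min_pts = min_pts, eps = Inf),
            class = "fc_reachability")
}
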