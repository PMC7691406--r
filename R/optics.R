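# From-scratch OPTICS, reachability-plot cluster extraction and the
# separation index summarizing cluster distinctness.

#' OPTICS ordering and reachability profile
#'
#' Classical OPTICS: points are processed in order of smallest current
#' reachability (ties broken by lowest point index), where the *core
#' distance* of a point is the distance to its `min_pts`-th nearest point
#' (the point itself counted, matching the DBSCAN neighborhood convention;
#' undefined, `Inf`, if beyond the generating distance `eps`) and the
#' *reachability* of a point from a processed core point `s` is
#' `max(core_dist(s), dist(s, p))`. The first point of the ordering (and
#' the first point of every new connected component) has undefined
#' reachability, stored as `Inf`.
#'
#' @param x Points matrix or [fc_features].
#' @param min_pts Neighborhood size parameter (default 15, within the
#'   commonly recommended 10-20 band).
#' @param eps Generating distance; `NULL` (default) uses the maximum
#'   pairwise distance, which is always "large enough".
#' @return Object of class `fc_reachability`: `ordering` (permutation of
#'   point indices), `reach` and `core_dist` (aligned to `ordering`, `Inf`
#'   where undefined), `min_pts`, `eps`.
#' @export
run_optics <- function(x, min_pts = 15L, eps = NULL) {
  d <- dist_matrix(x)
  n <- nrow(d)
  min_pts <- as.integer(min_pts)
  stopifnot(min_pts >= 1L)
  if (is.null(eps)) eps <- max(d)
  if (eps <= 0) eps <- .Machine$double.eps
  core_dist <- vapply(seq_len(n), function(i) {
    cd <- sort(d[i, ])[min_pts]  # includes self at distance 0
    if (is.na(cd) || cd > eps) Inf else cd
  }, numeric(1))
  if (min_pts > n) core_dist[] <- Inf

  processed <- logical(n)
  reach <- rep(Inf, n)     # current best reachability per point
  out_order <- integer(n)
  out_reach <- numeric(n)
  pos <- 0L

  update_from <- function(p) {
    if (!is.finite(core_dist[p])) return(invisible())
    cand <- which(!processed & d[p, ] <= eps)
    if (!length(cand)) return(invisible())
    newr <- pmax(core_dist[p], d[p, cand])
    better <- newr < reach[cand]
    reach[cand[better]] <<- newr[better]
    invisible()
  }

  while (pos < n) {
    unproc <- which(!processed)
    finite_r <- unproc[is.finite(reach[unproc])]
    if (length(finite_r)) {
      # seed queue: smallest reachability, ties -> lowest index
      p <- finite_r[order(reach[finite_r], finite_r)][1L]
      r <- reach[p]
    } else {
      p <- unproc[1L]  # start a new component: undefined reachability
      r <- Inf
    }
    processed[p] <- TRUE
    pos <- pos + 1L
    out_order[pos] <- p
    out_reach[pos] <- r
    update_from(p)
  }
  structure(list(ordering = out_order, reach = out_reach,
                 core_dist = core_dist[out_order],
                 min_pts = min_pts, eps = eps),
            class = "fc_reachability")
}

#' @export
print.fc_reachability <- function(x, ...) {
  fin <- is.finite(x$reach)
  cat(sprintf(paste0("<fc_reachability> %d points (min_pts = %d, eps = %.4g); ",
                     "defined reach in [%.4g, %.4g]\n"),
              length(x$ordering), x$min_pts, x$eps,
              if (any(fin)) min(x$reach[fin]) else NA,
              if (any(fin)) max(x$reach[fin]) else NA))
  invisible(x)
}

#' Extract clusters from a reachability profile
#'
#' Scans the OPTICS ordering: a point whose reachability exceeds the
#' threshold starts a new cluster if its core distance is within the
#' threshold, and is an outlier otherwise; points with reachability within
#' the threshold join the current cluster. On core points this reproduces
#' the DBSCAN partition at radius equal to the threshold.
#'
#' @param profile An [run_optics()] result.
#' @param threshold Reachability threshold (> 0).
#' @return An [fc_clustering] (assignment in original point order).
#' @export
extract_clusters <- function(profile, threshold) {
  stopifnot(inherits(profile, "fc_reachability"), threshold > 0)
  n <- length(profile$ordering)
  lab_ord <- integer(n)
  cl <- 0L
  cur <- 0L
  for (i in seq_len(n)) {
    if (profile$reach[i] > threshold) {
      if (profile$core_dist[i] <= threshold) {
        cl <- cl + 1L
        cur <- cl
        lab_ord[i] <- cur
      } else {
        lab_ord[i] <- 0L
        cur <- 0L
      }
    } else {
      if (cur == 0L) {  # defensively open a cluster (cannot normally occur)
        cl <- cl + 1L
        cur <- cl
      }
      lab_ord[i] <- cur
    }
  }
  assignment <- integer(n)
  assignment[profile$ordering] <- lab_ord
  fc_clustering(assignment,
                params = list(method = "optics", threshold = threshold,
                              min_pts = profile$min_pts, eps = profile$eps))
}

#' Automatic reachability threshold
#'
#' Default extraction rule: sort the defined (finite) reachability values
#' and place the threshold at the midpoint of the largest consecutive gap,
#' splitting the values into a valley population (within-cluster) and a
#' peak population (between-cluster).
#'
#' @param profile An [run_optics()] result.
#' @return Positive scalar threshold.
#' @export
auto_threshold <- function(profile) {
  stopifnot(inherits(profile, "fc_reachability"))
  v <- sort(profile$reach[is.finite(profile$reach)])
  if (length(v) < 2L) stop("need at least 2 defined reachability values", call. = FALSE)
  gaps <- diff(v)
  if (max(gaps) == 0) {
    stop("all reachability values are equal; supply a manual threshold",
         call. = FALSE)
  }
  i <- which.max(gaps)
  (v[i] + v[i + 1L]) / 2
}

#' Separation index of a reachability plot
#'
#' For each extracted cluster `k`, bounded in the ordering by peaks at
#' positions `i` (the point opening cluster `k`) and `j` (the point opening
#' cluster `k + 1`), the separation index is the ratio of the mean bounding
#' peak height to the mean reachability of the points strictly between the
#' peaks:
#' `S_k = ((RP(i) + RP(j)) / 2) / mean(RP(i+1), ..., RP(j-1))`.
#' The first and last points of the plot are left out: an undefined bounding
#' peak (e.g. the `Inf` reachability opening the plot, or a missing right
#' boundary for the last cluster) is replaced by the nearest defined
#' bounding peak, and the plot's last point never enters a valley. Clusters
#' with an empty valley are skipped with a warning. The final index is the
#' arithmetic mean of the per-cluster values; higher values mean peaks that
#' tower over the valleys, i.e. more cleanly separated clusters.
#'
#' @param profile An [run_optics()] result.
#' @param clusters An [fc_clustering] aligned to the same points (e.g. from
#'   [extract_clusters()]).
#' @return Object of class `fc_separation`: `per_cluster` (data frame:
#'   cluster, s_k) and `mean_index`.
#' @export
separation_index <- function(profile, clusters) {
  stopifnot(inherits(profile, "fc_reachability"),
            inherits(clusters, "fc_clustering"))
  n <- length(profile$ordering)
  stopifnot(length(clusters$assignment) == n)
  lab_ord <- clusters$assignment[profile$ordering]
  ids <- unique(lab_ord[lab_ord > 0L])
  if (!length(ids)) stop("no clusters to score", call. = FALSE)
  starts <- vapply(ids, function(k) min(which(lab_ord == k)), integer(1))
  ends <- vapply(ids, function(k) max(which(lab_ord == k)), integer(1))
  ord <- order(starts)
  ids <- ids[ord]; starts <- starts[ord]; ends <- ends[ord]
  rp <- profile$reach
  kk <- length(ids)
  out <- data.frame(cluster = integer(0), s_k = numeric(0))
  skipped <- 0L
  for (k in seq_len(kk)) {
    i <- starts[k]
    if (k < kk) {
      j <- starts[k + 1L]
    } else {
      after <- which(seq_len(n) > ends[k] & rp > 0 & is.finite(rp))
      j <- if (length(after)) after[1L] else NA_integer_
    }
    peaks <- c(if (is.finite(rp[i])) rp[i],
               if (!is.na(j) && is.finite(rp[j])) rp[j])
    if (!length(peaks)) {
      skipped <- skipped + 1L
      next
    }
    valley_hi <- if (!is.na(j)) j - 1L else min(ends[k], n - 1L)
    if (valley_hi < i + 1L) {
      skipped <- skipped + 1L
      next
    }
    vv <- rp[seq.int(i + 1L, valley_hi)]
    vv <- vv[is.finite(vv)]
    if (!length(vv)) {
      skipped <- skipped + 1L
      next
    }
    s_k <- mean(peaks) / mean(vv)
    out <- rbind(out, data.frame(cluster = ids[k], s_k = s_k))
  }
  if (skipped > 0L) {
    warning(skipped, " cluster(s) skipped (empty valley or no defined peak)",
            call. = FALSE)
  }
  if (!nrow(out)) stop("no cluster had a scorable valley", call. = FALSE)
  structure(list(per_cluster = out, mean_index = mean(out$s_k)),
            class = "fc_separation")
}

#' @export
print.fc_separation <- function(x, ...) {
  cat(sprintf("<fc_separation> mean index %.4f over %d cluster(s)\n",
              x$mean_index, nrow(x$per_cluster)))
  invisible(x)
}

#' OPTICS with automatic threshold extraction
#'
#' Convenience wrapper: order with [run_optics()], pick the threshold with
#' [auto_threshold()], extract with [extract_clusters()].
#'
#' @inheritParams run_optics
#' @param threshold Manual threshold; `NULL` uses [auto_threshold()].
#' @return List with `clustering`, `profile`, `threshold`.
#' @export
optics_auto <- function(x, min_pts = 15L, eps = NULL, threshold = NULL) {
  profile <- run_optics(x, min_pts = min_pts, eps = eps)
  if (is.null(threshold)) threshold <- auto_threshold(profile)
  list(clustering = extract_clusters(profile, threshold),
       profile = profile, threshold = threshold)
}
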