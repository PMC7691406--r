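# Cluster purity against diagnostic labels, and cluster-to-group matching.

# All injective maps from `k` items into `g` slots, as a list of integer
# vectors (which slot each item gets). Exhaustive; intended for small k, g.
injective_maps <- function(k, g) {
  if (k == 0L) return(list(integer(0)))
  out <- list()
  rec <- function(chosen, remaining) {
    if (length(chosen) == k) {
      out[[length(out) + 1L]] <<- chosen
      return(invisible())
    }
    for (s in remaining) rec(c(chosen, s), setdiff(remaining, s))
    invisible()
  }
  rec(integer(0), seq_len(g))
  out
}

#' Match clusters to diagnostic groups
#'
#' One-to-one assignment of cluster labels to group labels maximizing total
#' agreement on the contingency table (exhaustive optimal matching; a
#' greedy largest-cell-first variant is available for sensitivity
#' analysis). Extra clusters (when counts differ) map to no group.
#'
#' @param pred An [fc_clustering].
#' @param truth Group-labels data frame covering the same points.
#' @param method `"optimal"` (default) or `"greedy"`.
#' @return Named integer-keyed character vector: for each cluster id (name)
#'   the matched group level, `NA` for unmatched clusters.
#' @export
match_clusters_to_groups <- function(pred, truth, method = c("optimal", "greedy")) {
  method <- match.arg(method)
  stopifnot(inherits(pred, "fc_clustering"))
  truth <- validate_labels(truth, n_expected = length(pred$assignment))
  if (pred$n_clusters == 0L) stop("no clusters to match", call. = FALSE)
  cl <- pred$assignment
  groups <- levels(truth$group)
  tab <- matrix(0L, pred$n_clusters, length(groups),
                dimnames = list(seq_len(pred$n_clusters), groups))
  inc <- cl > 0L
  tt <- table(cl[inc], truth$group[inc])
  tab[rownames(tt), colnames(tt)] <- tt

  k <- nrow(tab); g <- ncol(tab)
  map <- rep(NA_integer_, k)
  if (method == "optimal" && min(k, g) <= 8L) {
    if (k <= g) {
      cands <- injective_maps(k, g)
      scores <- vapply(cands, function(m) sum(tab[cbind(seq_len(k), m)]),
                       numeric(1))
      map <- cands[[which.max(scores)]]
    } else {
      cands <- injective_maps(g, k)  # assign groups into clusters
      scores <- vapply(cands, function(m) sum(tab[cbind(m, seq_len(g))]),
                       numeric(1))
      best <- cands[[which.max(scores)]]
      map[best] <- seq_len(g)
    }
  } else {
    if (method == "optimal") {
      warning("too many clusters/groups for exhaustive matching; using greedy",
              call. = FALSE)
    }
    work <- tab
    repeat {
      if (!any(work >= 0)) break
      idx <- which(work == max(work), arr.ind = TRUE)[1L, , drop = TRUE]
      if (work[idx[1L], idx[2L]] < 0) break
      map[idx[1L]] <- idx[2L]
      work[idx[1L], ] <- -1L
      work[, idx[2L]] <- -1L
      if (all(is.na(map) == FALSE) || all(work < 0)) break
    }
  }
  stats::setNames(ifelse(is.na(map), NA_character_, groups[map]),
                  seq_len(k))
}

#' Cluster purity against known groups
#'
#' Overall purity is the percentage of subjects whose assigned cluster maps
#' to their true group under the optimal one-to-one matching; outliers
#' (label 0) count in the denominator and never as correct. Per-group
#' success rates are each group's members found in its matched cluster,
#' over the full group size. When the number of clusters differs from the
#' number of groups, unmatched clusters score nothing and unmatched groups
#' rate 0%, with a warning.
#'
#' @param pred An [fc_clustering].
#' @param truth Group-labels data frame.
#' @param method Matching rule, see [match_clusters_to_groups()].
#' @return Object of class `fc_purity`: `overall_purity` (percent),
#'   `per_group` (data frame: group, success_rate), `matching`,
#'   `n_outliers`.
#' @export
purity <- function(pred, truth, method = "optimal") {
  stopifnot(inherits(pred, "fc_clustering"))
  truth <- validate_labels(truth, n_expected = length(pred$assignment))
  n <- length(pred$assignment)
  if (pred$n_clusters == 0L) {
    matching <- character(0)
    correct <- 0L
    per_group <- data.frame(group = levels(truth$group),
                            success_rate = 0,
                            stringsAsFactors = FALSE)
  } else {
    matching <- match_clusters_to_groups(pred, truth, method = method)
    if (pred$n_clusters != nlevels(truth$group)) {
      warning(sprintf("%d cluster(s) for %d group(s); unmatched entities score 0",
                      pred$n_clusters, nlevels(truth$group)), call. = FALSE)
    }
    mapped <- rep(NA_character_, n)
    inc <- pred$assignment > 0L
    mapped[inc] <- matching[as.character(pred$assignment[inc])]
    correct <- sum(!is.na(mapped) & mapped == as.character(truth$group))
    per_group <- do.call(rbind, lapply(levels(truth$group), function(gl) {
      members <- truth$group == gl
      cl_for_g <- names(matching)[!is.na(matching) & matching == gl]
      hit <- if (length(cl_for_g)) {
        sum(members & pred$assignment == as.integer(cl_for_g[1L]))
      } else 0L
      data.frame(group = gl, success_rate = 100 * hit / sum(members),
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(overall_purity = 100 * correct / n,
                 per_group = per_group,
                 matching = matching,
                 n_outliers = sum(pred$assignment == 0L)),
            class = "fc_purity")
}

#' @export
print.fc_purity <- function(x, ...) {
  cat(sprintf("<fc_purity> overall %.2f%%, %d outlier(s)\n",
              x$overall_purity, x$n_outliers))
  for (i in seq_len(nrow(x$per_group))) {
    cat(sprintf("  %-8s %6.2f%%\n", x$per_group$group[i],
                x$per_group$success_rate[i]))
  }
  invisible(x)
}
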