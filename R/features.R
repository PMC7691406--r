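# Connectivity features: static FC, sliding-window dynamic FC variance,
# and covariate-adjusted top-k feature selection.

#' Static functional connectivity of one subject
#'
#' Pearson correlation between all ROI pairs of a timepoints-by-ROIs matrix,
#' giving a symmetric ROI-by-ROI matrix with unit diagonal.
#'
#' @param x Numeric matrix, timepoints x ROIs (or an [fc_timeseries], in
#'   which case a ROIs x ROIs x subjects array is returned).
#' @return Correlation matrix (or array for a whole cohort).
#' @export
static_fc <- function(x) {
  if (inherits(x, "fc_timeseries")) {
    d <- dim(x$data)
    out <- array(NA_real_, c(d[2L], d[2L], d[1L]),
                 dimnames = list(x$roi_ids, x$roi_ids, x$subject_ids))
    for (s in seq_len(d[1L])) out[, , s] <- static_fc(t(x$data[s, , ]))
    return(out)
  }
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 timepoints", call. = FALSE)
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(x)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop("correlation undefined: zero-variance series for ROI(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  r <- stats::cor(x)
  r[r > 1] <- 1
  r[r < -1] <- -1
  diag(r) <- 1
  r
}

#' Sliding-window Pearson correlation of two series
#'
#' Windows of length `w` advance one timepoint at a time; element `t` of the
#' output is the Pearson correlation of `x[t..t+w-1]` and `y[t..t+w-1]`.
#' Windows in which either series has zero variance yield `NA` (flagged with
#' a warning) and are excluded from downstream variance computations.
#'
#' @param x,y Numeric series of equal length `T >= w`.
#' @param w Window length (>= 2).
#' @return Numeric vector of length `T - w + 1` with values in `[-1, 1]`
#'   (or `NA` for degenerate windows).
#' @export
sliding_window_corr <- function(x, y, w) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("`x` and `y` must have equal length", call. = FALSE)
  w <- as.integer(w)
  if (w < 2L) stop("window length must be >= 2", call. = FALSE)
  tt <- length(x)
  if (tt < w) stop("series shorter than the window", call. = FALSE)
  nw <- tt - w + 1L
  roll <- function(v) {
    cs <- cumsum(v)
    cs[w:tt] - c(0, cs[seq_len(tt - w)])
  }
  sx <- roll(x); sy <- roll(y)
  sxx <- roll(x^2); syy <- roll(y^2); sxy <- roll(x * y)
  vx <- sxx - sx^2 / w
  vy <- syy - sy^2 / w
  cxy <- sxy - sx * sy / w
  denom2 <- vx * vy
  bad <- denom2 <= .Machine$double.eps * pmax(sxx, syy, 1)
  r <- rep(NA_real_, nw)
  r[!bad] <- cxy[!bad] / sqrt(denom2[!bad])
  r[r > 1] <- 1
  r[r < -1] <- -1
  if (any(bad)) {
    warning(sum(bad), " window(s) with zero variance flagged as NA", call. = FALSE)
  }
  r
}

#' Variance of a windowed-correlation series
#'
#' Sample variance (divisor `n - 1`) of the valid (non-`NA`) entries of a
#' sliding-window correlation series; the dynamic-connectivity feature.
#'
#' @param corr_series Numeric vector, typically from [sliding_window_corr()].
#' @return Non-negative scalar.
#' @export
dfc_variance <- function(corr_series) {
  v <- corr_series[is.finite(corr_series)]
  if (length(v) < 2L) {
    stop("need at least 2 valid windowed correlations", call. = FALSE)
  }
  stats::var(v)
}

# Sliding-window correlations for many pairs at once via running sums,
# processed in chunks of pairs to keep the working set cache-sized.
# X: timepoints x ROIs; pairs: 2-column index matrix.
# Returns n_windows x n_pairs matrix (NA for zero-variance windows).
sliding_corr_pairs <- function(x, w, pairs, chunk = 4000L) {
  tt <- nrow(x)
  nw <- tt - w + 1L
  colroll <- function(m) {
    cs <- m
    for (t in 2:tt) cs[t, ] <- cs[t - 1L, ] + m[t, ]
    cs[w:tt, , drop = FALSE] -
      rbind(0, cs[seq_len(tt - w), , drop = FALSE])
  }
  sx <- colroll(x)
  vroi <- colroll(x^2) - sx^2 / w  # per-ROI windowed sum of squares, centered
  out <- matrix(NA_real_, nw, nrow(pairs))
  for (st in seq.int(1L, nrow(pairs), by = chunk)) {
    en <- min(st + chunk - 1L, nrow(pairs))
    a <- pairs[st:en, 1L]; b <- pairs[st:en, 2L]
    sxy <- colroll(x[, a, drop = FALSE] * x[, b, drop = FALSE])
    cxy <- sxy - sx[, a, drop = FALSE] * sx[, b, drop = FALSE] / w
    denom2 <- vroi[, a, drop = FALSE] * vroi[, b, drop = FALSE]
    r <- cxy / sqrt(denom2)
    r[denom2 <= .Machine$double.eps] <- NA_real_
    out[, st:en] <- r
  }
  out[out > 1] <- 1
  out[out < -1] <- -1
  out
}

upper_pairs <- function(n_rois) {
  idx <- which(upper.tri(matrix(0, n_rois, n_rois)), arr.ind = TRUE)
  # order by (row, col) for a deterministic, readable feature order
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  colnames(idx) <- c("roi_a", "roi_b")
  idx
}

#' Covariate-adjusted top-k feature selection
#'
#' For each feature, fits the linear model
#' `feature ~ group + age + gender + motion` and computes the F-test for the
#' group term (mass-univariate analysis of covariance). The `k` features
#' with the smallest p-values are returned in ascending-p order, ties broken
#' by feature index.
#'
#' @param fm An [fc_features] object or numeric matrix (subjects x features).
#' @param labels Group-labels data frame (see [validate_labels()]).
#' @param k Number of features to keep (`k <= ncol`).
#' @param fisher_z Apply the Fisher z-transform `atanh` to the feature values
#'   before testing (values clamped away from +/-1); off by default.
#' @param alpha Optional significance gate: keep only features with
#'   `p < alpha` before ranking (may return fewer than `k` columns).
#' @return List with `features` (an [fc_features] with `k` columns) and
#'   `stats` (data frame: feature, F, p, rank for every candidate feature).
#' @export
select_top_features <- function(fm, labels, k, fisher_z = FALSE, alpha = NULL) {
  y <- feature_values(fm)
  labels <- validate_labels(labels, n_expected = nrow(y))
  if (nlevels(droplevels(labels$group)) < 2L) {
    stop("need at least 2 groups", call. = FALSE)
  }
  if (k > ncol(y)) stop("`k` exceeds the number of features", call. = FALSE)
  yt <- y
  if (fisher_z) yt <- atanh(pmin(pmax(y, -1 + 1e-12), 1 - 1e-12))

  xf <- stats::model.matrix(~ group + age + gender + motion, data = labels)
  xr <- stats::model.matrix(~ age + gender + motion, data = labels)
  qrf <- qr(xf)
  if (qrf$rank < ncol(xf)) {
    bad <- colnames(xf)[qrf$pivot[(qrf$rank + 1L):ncol(xf)]]
    stop("rank-deficient covariate design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  qf <- qr.Q(qrf)
  qr_r <- qr(xr)
  qred <- qr.Q(qr_r)
  tot <- colSums(yt^2)
  rss_f <- tot - colSums(crossprod(qf, yt)^2)
  rss_r <- tot - colSums(crossprod(qred, yt)^2)
  df1 <- ncol(xf) - qr_r$rank
  df2 <- nrow(y) - ncol(xf)
  fstat <- pmax(0, (rss_r - rss_f) / df1) / (rss_f / df2)
  pval <- stats::pf(fstat, df1, df2, lower.tail = FALSE)

  ord <- order(pval, seq_along(pval))
  stats_df <- data.frame(
    feature = colnames(y),
    F = fstat,
    p = pval,
    rank = match(seq_along(pval), ord),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  keep <- ord
  if (!is.null(alpha)) keep <- keep[pval[keep] < alpha]
  keep <- keep[seq_len(min(k, length(keep)))]
  fi <- if (inherits(fm, "fc_features") && !is.null(fm$feature_info)) {
    fm$feature_info[keep, , drop = FALSE]
  } else NULL
  list(
    features = fc_features(y[, keep, drop = FALSE], feature_info = fi),
    stats = stats_df
  )
}

#' Static and dynamic connectivity feature matrices for a cohort
#'
#' Vectorizes, for every ROI pair (upper triangle), the static Pearson
#' correlation (SFC) and the variance of sliding-window correlations
#' (DFC variance, window length chosen by [choose_window_length()]), then
#' applies [select_top_features()] to each family independently with the
#' same `k`.
#'
#' @param ts An [fc_timeseries] object.
#' @param labels Group-labels data frame.
#' @param spec A [window_spec()] for the adaptive window length.
#' @param k Features to retain per family (default 100).
#' @param window_length Optional fixed window length, bypassing the
#'   stationarity search.
#' @param families Which feature families to build (`"sfc"`, `"dfc"` or
#'   both, the default); skipping the dynamic family avoids the
#'   sliding-window pass entirely.
#' @return List with `sfc` and/or `dfc` (each as returned by
#'   [select_top_features()]) and `window_length` (`NA` when only the
#'   static family is built without a supplied length).
#' @export
build_feature_matrices <- function(ts, labels, spec = window_spec(), k = 100L,
                                   window_length = NULL,
                                   families = c("sfc", "dfc")) {
  stopifnot(inherits(ts, "fc_timeseries"))
  families <- match.arg(families, several.ok = TRUE)
  d <- dim(ts$data)
  labels <- validate_labels(labels, n_expected = d[1L])
  pairs <- upper_pairs(d[2L])
  np <- nrow(pairs)
  want_dfc <- "dfc" %in% families
  if (want_dfc && is.null(window_length)) {
    window_length <- choose_window_length(ts, spec)
  }
  w <- if (is.null(window_length)) NA_integer_ else as.integer(window_length)

  sfc <- matrix(NA_real_, d[1L], np)
  dfcv <- if (want_dfc) matrix(NA_real_, d[1L], np)
  for (s in seq_len(d[1L])) {
    x <- t(ts$data[s, , ])
    cm <- static_fc(x)
    sfc[s, ] <- cm[pairs]
    if (want_dfc) {
      rmat <- sliding_corr_pairs(x, w, pairs)
      nobs <- colSums(is.finite(rmat))
      mu <- colSums(rmat, na.rm = TRUE) / nobs
      ss <- colSums(rmat^2, na.rm = TRUE) - nobs * mu^2
      v <- ss / (nobs - 1L)
      v[nobs < 2L] <- NA_real_
      v[v < 0] <- 0  # guard against catastrophic cancellation
      dfcv[s, ] <- v
    }
  }
  if (want_dfc && anyNA(dfcv)) {
    warning("some pairs had too few valid windows; their DFC variance is 0",
            call. = FALSE)
    dfcv[is.na(dfcv)] <- 0
  }
  pair_ids <- sprintf("%s-%s", ts$roi_ids[pairs[, 1L]], ts$roi_ids[pairs[, 2L]])
  info <- function(measure) data.frame(
    feature = paste0(pair_ids, "_", measure),
    roi_a = ts$roi_ids[pairs[, 1L]],
    roi_b = ts$roi_ids[pairs[, 2L]],
    measure = measure,
    stringsAsFactors = FALSE
  )
  out <- list(window_length = w)
  if ("sfc" %in% families) {
    dimnames(sfc) <- list(ts$subject_ids, paste0(pair_ids, "_SFC"))
    out$sfc <- select_top_features(fc_features(sfc, feature_info = info("SFC")),
                                   labels, k)
  }
  if (want_dfc) {
    dimnames(dfcv) <- list(ts$subject_ids, paste0(pair_ids, "_DFCvar"))
    out$dfc <- select_top_features(fc_features(dfcv, feature_info = info("DFCvar")),
                                   labels, k)
  }
  out
}
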