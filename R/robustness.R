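# R-CLAN: recursive clustering using additive noise. An SNR ladder from
# high to low signal-to-noise, terminating at the first rung where cluster
# purity departs from its baseline.

#' Signal power of a feature matrix
#'
#' Mean squared value over every cell -- the `S` in `SNR = 10 log10(S / N)`.
#'
#' @param values Numeric matrix or [fc_features].
#' @return Positive scalar.
#' @export
signal_power <- function(values) {
  v <- feature_values(values)
  if (!length(v)) stop("empty matrix", call. = FALSE)
  s <- mean(v^2)
  if (s == 0) stop("all-zero matrix: SNR undefined", call. = FALSE)
  s
}

#' Noise power for a target SNR
#'
#' Inverts `SNR = 10 * log10(S / N)`: `N = S / 10^(snr_db / 10)`.
#'
#' @param s Signal power (> 0).
#' @param snr_db Target signal-to-noise ratio in decibels.
#' @return Noise power (variance of the additive Gaussian noise).
#' @export
noise_power_for_snr <- function(s, snr_db) {
  stopifnot(s > 0)
  s / 10^(snr_db / 10)
}

#' Corrupt features with white Gaussian noise at a target SNR
#'
#' Adds i.i.d. zero-mean Gaussian noise with variance
#' `noise_power_for_snr(signal_power(fm), snr_db)` to every cell. The input
#' is untouched; randomness comes from the current RNG state, so seed
#' beforehand for reproducibility.
#'
#' @param fm Numeric matrix or [fc_features].
#' @param snr_db Target SNR in dB.
#' @return Object of the same kind as `fm` with noisy values.
#' @export
corrupt_with_noise <- function(fm, snr_db) {
  v <- feature_values(fm)
  n_pow <- noise_power_for_snr(signal_power(v), snr_db)
  noisy <- v + matrix(stats::rnorm(length(v), sd = sqrt(n_pow)),
                      nrow(v), ncol(v))
  if (inherits(fm, "fc_features")) {
    fc_features(noisy, feature_info = fm$feature_info)
  } else {
    noisy
  }
}

#' R-CLAN configuration
#'
#' @param snr_start First-rung SNR in dB (default 100).
#' @param snr_step Decrement per rung in dB (default 1).
#' @param snr_floor Lowest SNR attempted; reaching it without a purity
#'   change censors the result (default 0).
#' @param replicates_per_snr Noise draws per rung; with more than one, the
#'   rung's purity is the majority vote across replicates (default 1).
#' @param seed Integer seed for the noise stream.
#' @param refit_params If `TRUE` the clusterer is expected to re-select its
#'   parameters on each corrupted matrix (use a refitting clusterer such as
#'   [clusterer_dbscan_auto()]); the default `FALSE` isolates the noise
#'   sensitivity of clustering itself by reusing clean-data parameters.
#' @return Object of class `rclan_config`.
#' @export
rclan_config <- function(snr_start = 100, snr_step = 1, snr_floor = 0,
                         replicates_per_snr = 1L, seed = 1L,
                         refit_params = FALSE) {
  stopifnot(snr_start > snr_floor, snr_step > 0, replicates_per_snr >= 1L)
  structure(list(snr_start = snr_start, snr_step = snr_step,
                 snr_floor = snr_floor,
                 replicates_per_snr = as.integer(replicates_per_snr),
                 seed = as.integer(seed),
                 refit_params = isTRUE(refit_params)),
            class = "rclan_config")
}

#' Fixed-parameter clusterer factories
#'
#' `r_clan()` takes the clustering procedure as a function mapping a feature
#' matrix to an [fc_clustering]. These factories build the common cases:
#' DBSCAN / OPTICS-extraction with parameters frozen from the clean data
#' (`clusterer_dbscan()`, `clusterer_optics()`), or re-selected on every
#' corrupted matrix (`clusterer_dbscan_auto()`, `clusterer_optics_auto()`).
#'
#' @param eps DBSCAN radius.
#' @param min_pts Neighborhood size parameter.
#' @param threshold Reachability-extraction threshold.
#' @param grid_size Epsilon-plot grid size for the refitting variant.
#' @return A function `(matrix) -> fc_clustering`.
#' @name clusterer_factories
NULL

#' @rdname clusterer_factories
#' @export
clusterer_dbscan <- function(eps, min_pts = 10L) {
  force(eps); force(min_pts)
  function(x) run_dbscan(x, eps = eps, min_pts = min_pts)
}

#' @rdname clusterer_factories
#' @export
clusterer_optics <- function(threshold, min_pts = 15L) {
  force(threshold); force(min_pts)
  function(x) extract_clusters(run_optics(x, min_pts = min_pts), threshold)
}

#' @rdname clusterer_factories
#' @export
clusterer_dbscan_auto <- function(min_pts = 10L, grid_size = 200L) {
  function(x) dbscan_auto(x, min_pts = min_pts, grid_size = grid_size)$clustering
}

#' @rdname clusterer_factories
#' @export
clusterer_optics_auto <- function(min_pts = 15L) {
  function(x) optics_auto(x, min_pts = min_pts)$clustering
}

#' Recursive clustering using additive noise (R-CLAN)
#'
#' Starting from `snr_start`, the *original* feature matrix is corrupted
#' afresh at each rung's SNR, clustered, and scored for overall purity
#' against the true groups. The ladder descends by `snr_step` per rung and
#' terminates at the first rung whose purity differs from the baseline
#' purity at `snr_start`; that rung's SNR is the *terminating SNR*, the
#' robustness measure (lower = more robust, because the structure survived
#' more noise). Reaching `snr_floor` without a change censors the result.
#' A clusterer failure at a rung is treated as a structure change (with a
#' warning).
#'
#' @param fm Numeric matrix or [fc_features]: the clean features.
#' @param truth Group-labels data frame (see [validate_labels()]).
#' @param clusterer Function mapping a feature matrix to an
#'   [fc_clustering]; see [clusterer_dbscan()] and friends.
#' @param config An [rclan_config()].
#' @return Object of class `fc_rclan`: `trace` (data frame snr_db, purity),
#'   `terminating_snr` (`NA` if censored), `censored`, `baseline_purity`,
#'   `config`.
#' @export
r_clan <- function(fm, truth, clusterer, config = rclan_config()) {
  stopifnot(inherits(config, "rclan_config"), is.function(clusterer))
  v <- feature_values(fm)
  truth <- validate_labels(truth, n_expected = nrow(v))
  set.seed(config$seed)
  snrs <- seq(config$snr_start, config$snr_floor, by = -config$snr_step)

  rung_purity <- function(snr) {
    reps <- vapply(seq_len(config$replicates_per_snr), function(i) {
      noisy <- corrupt_with_noise(v, snr)
      cl <- clusterer(noisy)
      purity(cl, truth)$overall_purity
    }, numeric(1))
    if (length(reps) == 1L) return(reps)
    tab <- table(reps)
    as.numeric(names(tab)[which.max(tab)])  # majority vote
  }

  trace <- data.frame(snr_db = numeric(0), purity = numeric(0))
  baseline <- NULL
  terminating <- NA_real_
  for (snr in snrs) {
    p <- tryCatch(rung_purity(snr), error = function(e) {
      warning(sprintf("clusterer failed at %g dB (%s); treated as a structure change",
                      snr, conditionMessage(e)), call. = FALSE)
      NA_real_
    })
    trace <- rbind(trace, data.frame(snr_db = snr,
                                     purity = if (is.na(p)) NA_real_ else p))
    if (is.null(baseline)) {
      if (is.na(p)) stop("clusterer failed at the baseline SNR", call. = FALSE)
      baseline <- p
      next
    }
    if (is.na(p) || abs(p - baseline) > 1e-9) {
      terminating <- snr
      break
    }
  }
  structure(list(trace = trace, terminating_snr = terminating,
                 censored = is.na(terminating), baseline_purity = baseline,
                 config = config),
            class = "fc_rclan")
}

#' @export
print.fc_rclan <- function(x, ...) {
  if (x$censored) {
    cat(sprintf("<fc_rclan> censored at floor %g dB (baseline purity %.2f%%)\n",
                x$config$snr_floor, x$baseline_purity))
  } else {
    cat(sprintf("<fc_rclan> terminating SNR %g dB (baseline purity %.2f%%)\n",
                x$terminating_snr, x$baseline_purity))
  }
  invisible(x)
}
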