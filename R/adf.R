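# Augmented Dickey-Fuller test (constant, no trend) and the adaptive
# window-length rule built on it.

# tau_mu critical values (regression with constant, no trend), indexed by
# sample size; standard Dickey-Fuller tabulation, interpolated in 1/n.
.adf_crit_table <- list(
  n = c(25, 50, 100, 250, 500, Inf),
  `0.01` = c(-3.75, -3.58, -3.51, -3.46, -3.44, -3.43),
  `0.05` = c(-3.00, -2.93, -2.89, -2.88, -2.87, -2.86),
  `0.10` = c(-2.63, -2.60, -2.58, -2.57, -2.57, -2.57)
)

adf_critical_value <- function(n, alpha = 0.05) {
  key <- sprintf("%.2f", alpha)
  if (!key %in% c("0.01", "0.05", "0.10")) {
    stop("`alpha` must be one of 0.01, 0.05, 0.10", call. = FALSE)
  }
  cv <- .adf_crit_table[[key]]
  tab_n <- .adf_crit_table$n
  # interpolate in 1/n (flat beyond the tabulated range)
  x <- 1 / pmin(pmax(n, tab_n[1L]), 1e9)
  stats::approx(1 / tab_n, cv, xout = x, rule = 2)$y
}

#' Augmented Dickey-Fuller unit-root test
#'
#' Dickey-Fuller regression with a constant and no trend:
#' `diff(x)[t] = a + g * x[t-1] + sum_i d_i * diff(x)[t-i] + e[t]`, testing
#' `g = 0` (unit root) against `g < 0` (stationarity) with the tau_mu
#' critical values. The lag order is chosen by AIC over `0:max_lags` on a
#' common estimation sample.
#'
#' @param x Numeric series (length >= 8 after differencing/lagging).
#' @param max_lags Maximum augmentation lag; default
#'   `trunc((length(x) - 1)^(1/3))`, capped so enough residual degrees of
#'   freedom remain.
#' @param alpha Test level: 0.01, 0.05 or 0.10.
#' @return List with `statistic` (tau), `lags` (selected lag order),
#'   `critical` (tau_mu critical value at `alpha`) and `reject` (`TRUE` if
#'   the unit-root null is rejected, i.e. the series looks stationary).
#' @export
adf_test <- function(x, max_lags = NULL, alpha = 0.05) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 8L) stop("series too short for the ADF regression", call. = FALSE)
  if (stats::sd(x) == 0) stop("constant series: ADF test undefined", call. = FALSE)
  if (is.null(max_lags)) max_lags <- trunc((n - 1)^(1 / 3))
  max_lags <- max(0L, min(as.integer(max_lags), n - 6L))

  dx <- diff(x)
  fit_lag <- function(p, common_start) {
    # rows t = start..(n-1) of dx used as response (dx[t] = x[t+1]-x[t])
    start <- max(p + 1L, common_start)
    idx <- start:(n - 1L)
    y <- dx[idx]
    xm <- cbind(1, x[idx])
    if (p > 0L) {
      lagmat <- sapply(seq_len(p), function(i) dx[idx - i])
      xm <- cbind(xm, lagmat)
    }
    fit <- stats::lm.fit(xm, y)
    rss <- sum(fit$residuals^2)
    k <- ncol(xm)
    neff <- length(y)
    list(rss = rss, k = k, neff = neff, fit = fit, xm = xm)
  }

  # lag selection by AIC on the common sample, then refit at the chosen lag
  # on its own maximal sample
  common_start <- max_lags + 1L
  if (max_lags > 0L) {
    aics <- vapply(0:max_lags, function(p) {
      f <- fit_lag(p, common_start)
      f$neff * log(f$rss / f$neff) + 2 * (f$k + 1L)
    }, numeric(1))
    p_sel <- (0:max_lags)[which.min(aics)]
  } else {
    p_sel <- 0L
  }
  f <- fit_lag(p_sel, 1L)
  sigma2 <- f$rss / (f$neff - f$k)
  xtx_inv <- chol2inv(chol(crossprod(f$xm)))
  se_g <- sqrt(sigma2 * xtx_inv[2L, 2L])
  stat <- f$fit$coefficients[2L] / se_g
  crit <- adf_critical_value(f$neff, alpha)
  list(statistic = unname(stat), lags = p_sel, critical = crit,
       reject = unname(stat < crit))
}

#' Sliding-window specification
#'
#' Parameters governing the adaptive window-length search and the sliding
#' windows themselves. Successive windows always differ by one timepoint
#' (stride 1).
#'
#' @param min_len,max_len Search range for the window length (timepoints).
#'   The default floor of 30 is the smallest length at which the
#'   Dickey-Fuller test has near-unit power on stationary white noise, so
#'   the 95%-of-windows rule below is attainable at all.
#' @param alpha Level of the stationarity (ADF) test.
#' @param reject_prop Fraction of windows that must reject the unit-root
#'   null for a candidate length to qualify (default 0.95).
#' @param adf_stride Evaluate the ADF test on every `adf_stride`-th window
#'   during the length search (1 = every window).
#' @param max_lags Maximum ADF augmentation lag. The window scan defaults
#'   to 0 (no augmentation): windows are short and augmentation lags cost
#'   power without protecting against anything the generator produces;
#'   `NULL` restores the automatic AIC choice of [adf_test()].
#' @param n_series When choosing one global window length for a cohort,
#'   number of ROI series pooled (sampled deterministically).
#' @return Object of class `window_spec`.
#' @export
window_spec <- function(min_len = 30L, max_len = 60L, alpha = 0.05,
                        reject_prop = 0.95, adf_stride = 1L,
                        max_lags = 0L, n_series = 50L) {
  stopifnot(min_len >= 2L, max_len >= min_len, alpha > 0, alpha < 1,
            reject_prop > 0, reject_prop <= 1, adf_stride >= 1L, n_series >= 1L)
  structure(list(min_len = as.integer(min_len), max_len = as.integer(max_len),
                 alpha = alpha, reject_prop = reject_prop,
                 adf_stride = as.integer(adf_stride), max_lags = max_lags,
                 n_series = as.integer(n_series)),
            class = "window_spec")
}

# Fraction of windows of length w (taken every `stride` starts) of each
# series in `series_list` that reject the ADF unit-root null.
adf_reject_fraction <- function(series_list, w, spec) {
  total <- 0L
  rejected <- 0L
  for (x in series_list) {
    tt <- length(x)
    starts <- seq.int(1L, tt - w + 1L, by = spec$adf_stride)
    for (s in starts) {
      win <- x[s:(s + w - 1L)]
      res <- tryCatch(
        adf_test(win, max_lags = spec$max_lags, alpha = spec$alpha),
        error = function(e) list(reject = FALSE)
      )
      total <- total + 1L
      rejected <- rejected + as.integer(isTRUE(res$reject))
    }
  }
  rejected / total
}

#' Adaptive window length from stationarity testing
#'
#' Returns the smallest window length `w` in `[min_len, max_len]` such that
#' at least `reject_prop` of the length-`w` windows of `x` reject the ADF
#' unit-root null at `alpha` (i.e. look stationary). If no length qualifies,
#' `max_len` is returned with attribute `nonstationary = TRUE`.
#'
#' @param x Numeric series.
#' @param spec A [window_spec()].
#' @return Integer window length with a logical attribute `nonstationary`.
#' @export
adf_window_length <- function(x, spec = window_spec()) {
  x <- as.numeric(x)
  if (length(x) < spec$min_len) {
    stop("series shorter than `min_len`", call. = FALSE)
  }
  if (spec$max_len > length(x)) {
    stop("`max_len` exceeds the series length", call. = FALSE)
  }
  if (stats::sd(x) == 0) {
    res <- spec$max_len
    attr(res, "nonstationary") <- TRUE
    return(res)
  }
  for (w in spec$min_len:spec$max_len) {
    frac <- adf_reject_fraction(list(x), w, spec)
    if (frac >= spec$reject_prop) {
      res <- as.integer(w)
      attr(res, "nonstationary") <- FALSE
      return(res)
    }
  }
  res <- spec$max_len
  attr(res, "nonstationary") <- TRUE
  res
}

#' One global window length for a cohort
#'
#' Pools up to `spec$n_series` ROI series (sampled deterministically on an
#' even subject-by-ROI lattice) and applies the [adf_window_length()] rule
#' to the pooled window population, so every subject and pair shares one
#' commensurable window length.
#'
#' @param ts An [fc_timeseries] object.
#' @param spec A [window_spec()].
#' @return Integer window length with attribute `nonstationary`.
#' @export
choose_window_length <- function(ts, spec = window_spec()) {
  stopifnot(inherits(ts, "fc_timeseries"))
  d <- dim(ts$data)
  if (spec$max_len > d[3L]) stop("`max_len` exceeds the series length", call. = FALSE)
  total <- d[1L] * d[2L]
  take <- unique(round(seq(1L, total, length.out = min(spec$n_series, total))))
  series_list <- lapply(take, function(i) {
    s <- ((i - 1L) %% d[1L]) + 1L
    r <- ((i - 1L) %/% d[1L]) + 1L
    ts$data[s, r, ]
  })
  keep <- vapply(series_list, function(x) stats::sd(x) > 0, logical(1))
  series_list <- series_list[keep]
  if (!length(series_list)) stop("all pooled series are constant", call. = FALSE)
  for (w in spec$min_len:spec$max_len) {
    frac <- adf_reject_fraction(series_list, w, spec)
    if (frac >= spec$reject_prop) {
      res <- as.integer(w)
      attr(res, "nonstationary") <- FALSE
      return(res)
    }
  }
  res <- spec$max_len
  attr(res, "nonstationary") <- TRUE
  res
}
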