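#' Synthetic cohort configuration
#'
#' Bundles every knob of the synthetic cohort generators. Defaults emulate the
#' study design the package targets: 132 subjects in four diagnostic groups
#' (35 controls, 34 early MCI, 34 late MCI, 29 Alzheimer's disease), 200
#' regions of interest (ROIs), 135 retained fMRI timepoints and 100 retained
#' connectivity features per measure.
#'
#' Two generators consume the same configuration but read the effect sizes on
#' different scales:
#' \itemize{
#'   \item [generate_feature_cohort()] works directly in feature space:
#'     `sfc_effect` is the pairwise distance between group centroids in units
#'     of `within_group_sd` (default 16 when left `NULL`).
#'   \item [generate_roi_timeseries()] works on the correlation scale:
#'     `sfc_effect` is the decline of the mean inter-ROI correlation from
#'     the first to the last group (default 0.45 when `NULL`) and
#'     `dfc_effect` the rise of the sinusoidal correlation-modulation
#'     amplitude (default 0.55 when `NULL`), which drives group differences
#'     in sliding-window correlation variance. The default
#'     `modulation_period` of 67.5 timepoints fits two full modulation
#'     cycles into the default scan, so the modulation averages out of the
#'     full-scan (static) correlation.
#' }
#'
#' @param group_sizes Integer vector of subjects per group.
#' @param n_rois Number of ROIs for time-series cohorts.
#' @param n_timepoints Retained timepoints per ROI series (>= 2).
#' @param n_features Number of features for feature-space cohorts.
#' @param sfc_effect Between-group shift of connectivity strength; `NULL`
#'   selects the generator-specific default described above. Must be >= 0.
#' @param dfc_effect Between-group shift of connectivity-variability
#'   amplitude; `NULL` selects the generator default. Must be >= 0.
#' @param within_group_sd Feature-space dispersion of each group (> 0).
#' @param n_affected_pairs Number of disjoint ROI pairs carrying the group
#'   effects; `NULL` means `floor(n_rois / 2)` (every ROI in one pair).
#' @param rho_base Baseline (control-group) inter-ROI correlation of
#'   affected pairs; static connectivity declines from it by `sfc_effect`
#'   across the group spectrum.
#' @param dfc_base Baseline correlation-modulation amplitude.
#' @param modulation_period Period, in timepoints, of the sinusoidal
#'   correlation modulation.
#' @param geometry `"simplex"` places group centroids equidistantly;
#'   `"spectrum"` places the intermediate groups on the line joining the
#'   first and last group, mimicking a disease continuum.
#' @param covariate_model List with `age_mean`, `age_sd`, `male_prop`
#'   (per-group vectors, recycled) and `motion_sd`; see
#'   [default_covariate_model()].
#' @param covariate_effect Strength of an optional age confound injected into
#'   the first features of feature-space cohorts (0 = no confounding, the
#'   default, so covariates are pure nuisance draws).
#' @param seed Integer seed; identical configurations and seeds give
#'   bit-identical cohorts.
#'
#' @return An object of class `cohort_config` (a validated list).
#' @seealso [generate_feature_cohort()], [generate_roi_timeseries()]
#' @export
cohort_config <- function(group_sizes = c(35L, 34L, 34L, 29L),
                          n_rois = 200L,
                          n_timepoints = 135L,
                          n_features = 100L,
                          sfc_effect = NULL,
                          dfc_effect = NULL,
                          within_group_sd = 1,
                          n_affected_pairs = NULL,
                          rho_base = 0.5,
                          dfc_base = 0.3,
                          modulation_period = 67.5,
                          geometry = c("simplex", "spectrum"),
                          covariate_model = default_covariate_model(length(group_sizes)),
                          covariate_effect = 0,
                          seed = 1L) {
  geometry <- match.arg(geometry)
  if (length(group_sizes) < 1L || any(group_sizes != round(group_sizes)) ||
      any(group_sizes <= 0)) {
    stop("`group_sizes` must be positive integers", call. = FALSE)
  }
  for (nm in c("n_rois", "n_timepoints", "n_features")) {
    v <- get(nm)
    if (length(v) != 1L || v != round(v) || v <= 0) {
      stop(sprintf("`%s` must be a positive integer", nm), call. = FALSE)
    }
  }
  if (n_timepoints < 2L) stop("`n_timepoints` must be >= 2", call. = FALSE)
  if (!is.null(sfc_effect) && (length(sfc_effect) != 1L || sfc_effect < 0)) {
    stop("`sfc_effect` must be a single value >= 0", call. = FALSE)
  }
  if (!is.null(dfc_effect) && (length(dfc_effect) != 1L || dfc_effect < 0)) {
    stop("`dfc_effect` must be a single value >= 0", call. = FALSE)
  }
  if (length(within_group_sd) != 1L || within_group_sd <= 0) {
    stop("`within_group_sd` must be > 0", call. = FALSE)
  }
  if (is.null(n_affected_pairs)) n_affected_pairs <- floor(n_rois / 2)
  if (n_affected_pairs != round(n_affected_pairs) || n_affected_pairs < 1) {
    stop("`n_affected_pairs` must be a positive integer", call. = FALSE)
  }
  if (2L * n_affected_pairs > n_rois) {
    stop("`n_affected_pairs` exceeds the number of disjoint ROI pairs ",
         "available (need 2 * n_affected_pairs <= n_rois)", call. = FALSE)
  }
  if (modulation_period <= 0) stop("`modulation_period` must be > 0", call. = FALSE)
  stopifnot(is.list(covariate_model))
  cfg <- list(
    group_sizes = as.integer(group_sizes),
    n_rois = as.integer(n_rois),
    n_timepoints = as.integer(n_timepoints),
    n_features = as.integer(n_features),
    sfc_effect = sfc_effect,
    dfc_effect = dfc_effect,
    within_group_sd = within_group_sd,
    n_affected_pairs = as.integer(n_affected_pairs),
    rho_base = rho_base,
    dfc_base = dfc_base,
    modulation_period = modulation_period,
    geometry = geometry,
    covariate_model = covariate_model,
    covariate_effect = covariate_effect,
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  cfg
}

#' Default nuisance-covariate model
#'
#' Per-group age means/SDs and male proportions follow the demographics of
#' the four-group cognitive-impairment cohort the generator emulates
#' (control, early MCI, late MCI, AD). Head motion is a unit-scale Gaussian
#' score with no group structure.
#'
#' @param n_groups Number of groups; the four reference rows are recycled.
#' @return List with `age_mean`, `age_sd`, `male_prop`, `motion_sd`.
#' @export
default_covariate_model <- function(n_groups = 4L) {
  rec <- function(x) rep_len(x, n_groups)
  list(
    age_mean = rec(c(74.5, 72.2, 71.4, 73.1)),
    age_sd = rec(c(5.9, 5.9, 8.6, 7.4)),
    male_prop = rec(c(15 / 36, 18 / 34, 21 / 34, 13 / 29)),
    motion_sd = 1
  )
}

group_level_names <- function(n_groups) {
  if (n_groups == 4L) c("control", "EMCI", "LMCI", "AD") else paste0("G", seq_len(n_groups))
}

subject_id_vec <- function(n) sprintf("sub%03d", seq_len(n))

# Per-subject group factor plus covariate draws; shared by both generators.
draw_labels <- function(cfg) {
  g <- length(cfg$group_sizes)
  lev <- group_level_names(g)
  grp <- factor(rep(lev, cfg$group_sizes), levels = lev)
  n <- length(grp)
  cm <- cfg$covariate_model
  idx <- as.integer(grp)
  age <- stats::rnorm(n, mean = cm$age_mean[idx], sd = cm$age_sd[idx])
  gender <- stats::rbinom(n, 1L, prob = cm$male_prop[idx])
  motion <- stats::rnorm(n, mean = 0, sd = cm$motion_sd)
  data.frame(
    subject = subject_id_vec(n),
    group = grp,
    age = age,
    gender = gender,
    motion = motion,
    stringsAsFactors = FALSE
  )
}

# Group centroids in feature space, pairwise distance `sep` apart (simplex)
# or spanning `sep` end to end (spectrum).
group_centroids <- function(n_groups, n_features, sep, geometry) {
  cen <- matrix(0, n_groups, n_features)
  if (geometry == "simplex") {
    if (n_features < n_groups) {
      stop("simplex geometry needs n_features >= number of groups", call. = FALSE)
    }
    for (g in seq_len(n_groups)) cen[g, g] <- sep / sqrt(2)
  } else {
    cen[, 1L] <- sep * (seq_len(n_groups) - 1L) / max(1L, n_groups - 1L)
  }
  cen
}

#' Generate a synthetic subject-by-feature cohort
#'
#' Draws each group's rows from a multivariate Gaussian whose centroid
#' geometry is controlled by `config$geometry`, with pairwise centroid
#' separation `sfc_effect * within_group_sd` and isotropic within-group
#' dispersion `within_group_sd`. Nuisance covariates (age, gender, motion)
#' are drawn per the covariate model; with `covariate_effect > 0` an age
#' confound is additionally injected into the first features so that
#' covariate-adjusted feature selection can be exercised under confounding.
#'
#' @param config A [cohort_config()].
#' @return List with `features` (an [fc_features] object, subjects x
#'   `n_features`) and `labels` (data frame: subject, group, age, gender,
#'   motion).
#' @examples
#' cohort <- generate_feature_cohort(cohort_config(seed = 1))
#' dim(cohort$features$values)  # 132 x 100
#' @export
generate_feature_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  sep_units <- if (is.null(config$sfc_effect)) 16 else config$sfc_effect
  set.seed(config$seed)
  labels <- draw_labels(config)
  n <- nrow(labels)
  p <- config$n_features
  cen <- group_centroids(length(config$group_sizes), p,
                         sep_units * config$within_group_sd, config$geometry)
  x <- cen[as.integer(labels$group), , drop = FALSE] +
    matrix(stats::rnorm(n * p, sd = config$within_group_sd), n, p)
  if (config$covariate_effect > 0) {
    k <- min(10L, p)
    zage <- as.numeric(scale(labels$age))
    x[, seq_len(k)] <- x[, seq_len(k)] +
      config$covariate_effect * config$within_group_sd * zage
  }
  dimnames(x) <- list(labels$subject, sprintf("F%04d", seq_len(p)))
  list(features = fc_features(x), labels = labels)
}

#' Generate synthetic ROI time series
#'
#' Produces per-subject ROI time series (subjects x ROIs x timepoints) in
#' which `n_affected_pairs` disjoint ROI pairs share a latent signal. The
#' instantaneous correlation of pair members follows
#' `rho(t) = rho0 + A * sin(2 * pi * t / period + phase)` with a random phase
#' per subject and pair: the group-specific level `rho0` (spread `sfc_effect`
#' across groups on the correlation scale) sets static connectivity, and the
#' group-specific amplitude `A` (spread `dfc_effect`) sets the variance of
#' sliding-window correlations, so the two feature families are dialled
#' independently. The second pair member is built as
#' `y_t = rho(t) x_t + sqrt(1 - rho(t)^2) e_t` with white Gaussian `x`, `e`,
#' so with constant mixing `rho` the long-run Pearson correlation converges
#' to `rho` itself. Unaffected ROIs are independent white Gaussian series.
#'
#' @param config A [cohort_config()].
#' @return List with `timeseries` (an [fc_timeseries] object; its
#'   `affected_pairs` element records the ground-truth ROI pairs) and
#'   `labels` as in [generate_feature_cohort()].
#' @export
generate_roi_timeseries <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  if (config$n_timepoints < 2L) stop("`n_timepoints` must be >= 2", call. = FALSE)
  sfc <- if (is.null(config$sfc_effect)) 0.45 else config$sfc_effect
  dfc <- if (is.null(config$dfc_effect)) 0.55 else config$dfc_effect
  set.seed(config$seed)
  labels <- draw_labels(config)
  n <- nrow(labels)
  r <- config$n_rois
  tt <- config$n_timepoints
  g <- length(config$group_sizes)
  lev <- (as.integer(labels$group) - 1L) / max(1L, g - 1L)
  # Disease spectrum: static connectivity declines from rho_base by
  # sfc_effect across groups, while the variability amplitude rises by
  # dfc_effect -- connectivity loss with greater temporal fluctuation.
  rho0 <- config$rho_base - sfc * lev
  amp <- config$dfc_base + dfc * lev
  npair <- config$n_affected_pairs
  pairs <- cbind(roi_a = 2L * seq_len(npair) - 1L, roi_b = 2L * seq_len(npair))
  dat <- array(NA_real_, dim = c(n, r, tt))
  tgrid <- seq_len(tt)
  for (s in seq_len(n)) {
    mat <- matrix(stats::rnorm(tt * r), tt, r)
    for (k in seq_len(npair)) {
      phase <- stats::runif(1L, 0, 2 * pi)
      rho_t <- rho0[s] + amp[s] * sin(2 * pi * tgrid / config$modulation_period + phase)
      rho_t <- pmin(pmax(rho_t, -0.95), 0.95)
      x <- mat[, pairs[k, 1L]]
      mat[, pairs[k, 2L]] <- rho_t * x + sqrt(1 - rho_t^2) * stats::rnorm(tt)
    }
    dat[s, , ] <- t(mat)
  }
  ts <- fc_timeseries(dat, subject_ids = labels$subject,
                      roi_ids = sprintf("ROI%03d", seq_len(r)),
                      affected_pairs = as.data.frame(pairs))
  list(timeseries = ts, labels = labels)
}

#' ROI time-series container
#'
#' @param data Numeric array, subjects x ROIs x timepoints, all finite.
#' @param subject_ids,roi_ids Identifier vectors matching the array extents.
#' @param affected_pairs Optional data frame of ground-truth affected ROI
#'   pairs (synthetic cohorts only).
#' @return Object of class `fc_timeseries`.
#' @export
fc_timeseries <- function(data, subject_ids = NULL, roi_ids = NULL,
                          affected_pairs = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (dim(data)[3L] < 2L) stop("need at least 2 timepoints", call. = FALSE)
  if (!all(is.finite(data))) stop("time series must be finite", call. = FALSE)
  if (is.null(subject_ids)) subject_ids <- subject_id_vec(dim(data)[1L])
  if (is.null(roi_ids)) roi_ids <- sprintf("ROI%03d", seq_len(dim(data)[2L]))
  stopifnot(length(subject_ids) == dim(data)[1L],
            length(roi_ids) == dim(data)[2L])
  structure(list(data = data, subject_ids = subject_ids, roi_ids = roi_ids,
                 affected_pairs = affected_pairs),
            class = "fc_timeseries")
}

#' @export
print.fc_timeseries <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<fc_timeseries> %d subjects x %d ROIs x %d timepoints\n",
              d[1L], d[2L], d[3L]))
  invisible(x)
}

#' Subject-by-feature matrix container
#'
#' A thin wrapper around a numeric matrix (subjects in rows, features in
#' columns) plus optional per-feature provenance (`feature_info`: which ROI
#' pair and which measure, SFC or DFCvar, a column came from).
#'
#' @param values Numeric matrix without missing values; row names are
#'   subject identifiers, column names feature identifiers.
#' @param feature_info Optional data frame with one row per column of
#'   `values` (columns `feature`, `roi_a`, `roi_b`, `measure`).
#' @return Object of class `fc_features`.
#' @export
fc_features <- function(values, feature_info = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values) || anyNA(values) || !all(is.finite(values))) {
    stop("feature values must be finite and non-missing", call. = FALSE)
  }
  if (is.null(rownames(values))) rownames(values) <- subject_id_vec(nrow(values))
  if (is.null(colnames(values))) colnames(values) <- sprintf("F%04d", seq_len(ncol(values)))
  if (anyDuplicated(rownames(values))) stop("duplicate subject ids", call. = FALSE)
  if (!is.null(feature_info)) {
    stopifnot(is.data.frame(feature_info), nrow(feature_info) == ncol(values))
  }
  structure(list(values = values, feature_info = feature_info),
            class = "fc_features")
}

#' @export
print.fc_features <- function(x, ...) {
  cat(sprintf("<fc_features> %d subjects x %d features\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
as.matrix.fc_features <- function(x, ...) x$values

# Accept either a bare matrix or an fc_features object.
feature_values <- function(x) {
  if (inherits(x, "fc_features")) x$values else as.matrix(x)
}

#' Validate a group-labels data frame
#'
#' Checks the contract shared by every stage: one row per subject, columns
#' `subject`, `group` (factor), `age`, `gender`, `motion`.
#'
#' @param labels Data frame to validate.
#' @param n_expected Optional expected number of subjects.
#' @return The validated data frame (group coerced to factor), invisibly
#'   usable in pipelines.
#' @export
validate_labels <- function(labels, n_expected = NULL) {
  need <- c("subject", "group", "age", "gender", "motion")
  missing_cols <- setdiff(need, names(labels))
  if (length(missing_cols)) {
    stop("labels missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(n_expected) && nrow(labels) != n_expected) {
    stop(sprintf("labels have %d rows, expected %d", nrow(labels), n_expected),
         call. = FALSE)
  }
  if (anyDuplicated(labels$subject)) stop("duplicate subject ids in labels", call. = FALSE)
  labels$group <- as.factor(labels$group)
  labels
}
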