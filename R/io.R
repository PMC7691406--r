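# Tabular I/O: features, labels, assignments, epsilon plots, reachability
# profiles, and the run manifest. All files are plain TSV/JSON; doubles are
# written with 17 significant digits so a write/read round trip is exact.

fmt_num <- function(x) {
  ifelse(is.finite(x), sprintf("%.17g", x),
         ifelse(is.infinite(x) & x > 0, "inf",
                ifelse(is.infinite(x), "-inf", "NA")))
}

parse_num <- function(x) {
  out <- suppressWarnings(as.numeric(ifelse(x == "inf", "Inf",
                                            ifelse(x == "-inf", "-Inf", x))))
  bad <- is.na(out) & !(x %in% c("NA", NA))
  if (any(bad)) stop("non-numeric cell(s): ", paste(utils::head(x[bad], 3), collapse = ", "),
                     call. = FALSE)
  out
}

#' Read and write feature matrices
#'
#' `features.tsv` layout: header row of feature identifiers, first column
#' `subject`, one row per subject. Values round-trip at full double
#' precision.
#'
#' @param fm An [fc_features] (or matrix) to write.
#' @param path File path.
#' @return `read_feature_matrix()` returns an [fc_features];
#'   `write_feature_matrix()` returns `path` invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  v <- feature_values(fm)
  df <- data.frame(subject = rownames(v), stringsAsFactors = FALSE)
  chr <- apply(v, 2L, fmt_num)
  if (is.null(dim(chr))) chr <- matrix(chr, nrow = nrow(v))
  colnames(chr) <- colnames(v)
  utils::write.table(cbind(df, chr), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE)
  if (!"subject" %in% names(df)) stop("missing `subject` column", call. = FALSE)
  if (anyDuplicated(df$subject)) {
    stop("duplicate subject id(s): ",
         paste(unique(df$subject[duplicated(df$subject)]), collapse = ", "),
         call. = FALSE)
  }
  vals <- vapply(df[setdiff(names(df), "subject")], parse_num,
                 numeric(nrow(df)))
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = nrow(df))
  rownames(vals) <- df$subject
  colnames(vals) <- setdiff(names(df), "subject")
  fc_features(vals)
}

#' Read and write group-label tables
#'
#' `labels.tsv` layout: columns subject, group, age, gender, motion. When
#' `features` is supplied, reading checks that every feature subject has a
#' label row.
#'
#' @param labels Labels data frame to write.
#' @param path File path.
#' @param features Optional [fc_features] for referential-integrity checks.
#' @return `read_labels()` returns the validated data frame.
#' @export
write_labels <- function(labels, path) {
  labels <- validate_labels(labels)
  out <- data.frame(subject = labels$subject,
                    group = as.character(labels$group),
                    age = fmt_num(labels$age),
                    gender = labels$gender,
                    motion = fmt_num(labels$motion),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path, features = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE)
  labels <- data.frame(subject = df$subject,
                       group = factor(df$group, levels = unique(df$group)),
                       age = parse_num(df$age),
                       gender = as.integer(df$gender),
                       motion = parse_num(df$motion),
                       stringsAsFactors = FALSE)
  labels <- validate_labels(labels)
  if (!is.null(features)) {
    miss <- setdiff(rownames(feature_values(features)), labels$subject)
    if (length(miss)) {
      stop("labels missing subject(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
  }
  labels
}

#' Write cluster assignments
#'
#' Two-column TSV `subject`, `cluster` (0 = outlier).
#'
#' @param clustering An [fc_clustering].
#' @param subjects Subject identifiers, same order as the assignment.
#' @param path File path.
#' @export
write_assignments <- function(clustering, subjects, path) {
  stopifnot(inherits(clustering, "fc_clustering"),
            length(subjects) == length(clustering$assignment))
  utils::write.table(
    data.frame(subject = subjects, cluster = clustering$assignment),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an epsilon plot as TSV
#'
#' Rows of (eps, n_clusters) for replotting the cluster-count-vs-radius
#' step curve.
#'
#' @param epsplot An `fc_epsplot` from [epsilon_plot_select()].
#' @param path File path.
#' @export
write_epsplot <- function(epsplot, path) {
  stopifnot(inherits(epsplot, "fc_epsplot"))
  utils::write.table(
    data.frame(eps = fmt_num(epsplot$eps_grid),
               n_clusters = epsplot$n_clusters_at),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a reachability profile as TSV
#'
#' Rows of (order_position, point_id, reach, core_dist); undefined values
#' are serialized as `inf`.
#'
#' @param profile An `fc_reachability` from [run_optics()].
#' @param subjects Optional subject identifiers (original point order).
#' @param path File path.
#' @export
write_reachability <- function(profile, path, subjects = NULL) {
  stopifnot(inherits(profile, "fc_reachability"))
  ids <- if (is.null(subjects)) as.character(profile$ordering) else subjects[profile$ordering]
  utils::write.table(
    data.frame(order_position = seq_along(profile$ordering),
               point_id = ids,
               reach = fmt_num(profile$reach),
               core_dist = fmt_num(profile$core_dist)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cohort configuration from YAML
#'
#' Reads a flat YAML mapping of [cohort_config()] arguments (requires the
#' `yaml` package).
#'
#' @param path YAML file path.
#' @return A [cohort_config()].
#' @export
read_cohort_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the `yaml` package is required to read YAML configs", call. = FALSE)
  }
  args <- yaml::read_yaml(path)
  known <- names(formals(cohort_config))
  unknown <- setdiff(names(args), known)
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(cohort_config, args)
}
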