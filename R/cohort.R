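# Cohort container: long-format repeated biomarker measurements, one row per
# measurement, grouped by subject.  Times are days since curettage, values are
# hCG concentrations in IU/L modelled on the natural-log scale.

#' Construct a cohort from a long-format data frame
#'
#' Low-level constructor.  Most users should call [read_cohort()] or
#' [simulate_cohort()] instead.
#'
#' @param data data frame with columns `subject_id`, `time`, `hcg`,
#'   `log_hcg`.  Rows are re-ordered by subject (file order of first
#'   appearance) and ascending time.
#' @param labels optional named vector (names = subject ids) of 0/1
#'   gold-standard disease labels.  Labels are never used during fitting,
#'   only by the diagnostic-accuracy functions.
#' @return an object of class `cohort`.
#' @export
new_cohort <- function(data, labels = NULL) {
  stopifnot(is.data.frame(data),
            all(c("subject_id", "time", "hcg", "log_hcg") %in% names(data)))
  data$subject_id <- as.character(data$subject_id)
  subjects <- unique(data$subject_id)
  data <- data[order(match(data$subject_id, subjects), data$time), , drop = FALSE]
  rownames(data) <- NULL
  if (anyDuplicated(paste(data$subject_id, data$time)))
    stop("duplicate (subject, time) pairs; resolve with the `dedup` policy of read_cohort()")
  if (any(data$time < 0)) stop("negative measurement times")
  if (any(!is.finite(data$hcg) | data$hcg <= 0))
    stop("non-positive hCG values for subject(s): ",
         paste(unique(data$subject_id[!is.finite(data$hcg) | data$hcg <= 0]),
               collapse = ", "))
  row_subject <- match(data$subject_id, subjects)
  counts <- tabulate(row_subject, nbins = length(subjects))
  if (!is.null(labels)) {
    if (is.null(names(labels))) names(labels) <- subjects
    labels <- labels[subjects]
    if (anyNA(labels)) stop("disease labels missing for some subjects")
    labels <- stats::setNames(as.integer(labels), subjects)
  }
  structure(
    list(data = data, subjects = subjects, row_subject = row_subject,
         counts = counts, labels = labels),
    class = "cohort")
}

#' Number of subjects / measurements in a cohort
#' @param cohort a `cohort` object
#' @return integer count
#' @export
n_subjects <- function(cohort) length(cohort$subjects)

#' @rdname n_subjects
#' @export
n_measurements <- function(cohort) nrow(cohort$data)

#' Read a longitudinal biomarker cohort from delimited text
#'
#' Expects a header and columns `subject_id`, `time_days`, `hcg` and
#' optionally `disease` (0/1 per subject).  The separator is auto-detected
#' from the extension (`.tsv`/`.tab` = tab, otherwise comma).  Applies the
#' inclusion filter used throughout: measurements after `horizon` days are
#' dropped, then subjects with fewer than `min_measurements` remaining rows
#' are dropped.
#'
#' hCG values must be strictly positive: the model works on the log scale,
#' so values below the assay detection limit must be pre-imputed to the
#' detection limit upstream.
#'
#' @param path file path.
#' @param horizon follow-up window in days (default 21).
#' @param min_measurements minimum retained measurements per subject
#'   (default 2).
#' @param dedup policy for duplicate (subject, time) rows: `"first"` keeps
#'   the first by file order (default), `"mean"` averages on the log scale,
#'   `"error"` refuses.
#' @return a [new_cohort()] object.
#' @export
read_cohort <- function(path, horizon = 21, min_measurements = 2,
                        dedup = c("first", "mean", "error")) {
  dedup <- match.arg(dedup)
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c("subject_id", "time_days", "hcg")
  if (!all(need %in% names(raw)))
    stop("input must have columns subject_id, time_days, hcg")
  if (nrow(raw) == 0) stop("no subjects after filtering")
  raw$subject_id <- as.character(raw$subject_id)
  bad <- !is.finite(raw$hcg) | raw$hcg <= 0
  if (any(bad))
    stop("non-positive hCG values for subject(s): ",
         paste(unique(raw$subject_id[bad]), collapse = ", "),
         " (pre-impute undetectable values to the assay detection limit)")
  if (any(raw$time_days < 0)) stop("negative time_days values")

  raw <- raw[raw$time_days <= horizon, , drop = FALSE]
  disease_by_subject <- if ("disease" %in% names(raw))
    tapply(raw$disease, raw$subject_id, function(x) x[1])
  key <- paste(raw$subject_id, raw$time_days)
  if (anyDuplicated(key)) {
    if (dedup == "error")
      stop("duplicate (subject, time) rows; resolve with dedup = \"first\" or dedup = \"mean\"")
    if (dedup == "first") {
      raw <- raw[!duplicated(key), , drop = FALSE]
    } else {
      lg <- stats::aggregate(list(lg = log(raw$hcg)),
                             by = list(subject_id = raw$subject_id,
                                       time_days = raw$time_days),
                             FUN = mean)
      raw2 <- data.frame(subject_id = lg$subject_id, time_days = lg$time_days,
                         hcg = exp(lg$lg), stringsAsFactors = FALSE)
      if (!is.null(disease_by_subject))
        raw2$disease <- as.vector(disease_by_subject[raw2$subject_id])
      raw <- raw2
    }
  }

  cnt <- table(raw$subject_id)
  keep <- names(cnt)[cnt >= min_measurements]
  raw <- raw[raw$subject_id %in% keep, , drop = FALSE]
  if (nrow(raw) == 0) stop("no subjects after filtering")

  labels <- NULL
  if ("disease" %in% names(raw)) {
    lab <- tapply(raw$disease, raw$subject_id, function(x) unique(x))
    if (any(lengths(lab) != 1))
      stop("inconsistent disease labels within subject(s)")
    labels <- stats::setNames(as.integer(unlist(lab)), names(lab))
  }
  new_cohort(data.frame(subject_id = raw$subject_id, time = raw$time_days,
                        hcg = raw$hcg, log_hcg = log(raw$hcg),
                        stringsAsFactors = FALSE),
             labels = labels)
}

#' Write a cohort back to delimited text
#'
#' Inverse of [read_cohort()] on the retained rows (separator again chosen
#' by extension).
#'
#' @param cohort a `cohort`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- data.frame(subject_id = cohort$data$subject_id,
                    time_days = cohort$data$time,
                    hcg = cohort$data$hcg, stringsAsFactors = FALSE)
  if (!is.null(cohort$labels))
    out$disease <- cohort$labels[out$subject_id]
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Summarize a cohort
#'
#' Reports subject and measurement counts, the per-subject measurement-count
#' distribution (median/min/max) and, when gold-standard labels are present,
#' the disease prevalence in percent.
#'
#' @param cohort a `cohort`.
#' @return a list with elements `n_subjects`, `n_measurements`,
#'   `measurements_per_subject` (median/min/max) and `prevalence`
#'   (percent, or `NULL` without labels).
#' @export
cohort_summary <- function(cohort) {
  if (n_subjects(cohort) == 0) stop("empty cohort")
  cnt <- cohort$counts
  list(
    n_subjects = n_subjects(cohort),
    n_measurements = n_measurements(cohort),
    measurements_per_subject = list(
      median = stats::median(cnt), min = min(cnt), max = max(cnt)),
    prevalence = if (!is.null(cohort$labels))
      100 * mean(cohort$labels == 1) else NULL)
}

#' Restrict a cohort to a subset of subjects
#'
#' @param cohort a `cohort`.
#' @param subjects character vector of subject ids (order preserved).
#' @return a `cohort` containing only those subjects.
#' @export
subset_cohort <- function(cohort, subjects) {
  if (!all(subjects %in% cohort$subjects)) stop("unknown subject ids")
  keep <- cohort$data$subject_id %in% subjects
  labels <- if (!is.null(cohort$labels)) cohort$labels[subjects]
  new_cohort(cohort$data[keep, , drop = FALSE], labels = labels)
}

#' Extract a single trajectory
#'
#' @param cohort a `cohort`.
#' @param subject subject id or integer index.
#' @return an object of class `trajectory`: time, hcg and log-hcg vectors
#'   plus the disease label when available.
#' @export
get_trajectory <- function(cohort, subject) {
  if (is.numeric(subject)) subject <- cohort$subjects[subject]
  i <- which(cohort$data$subject_id == subject)
  if (!length(i)) stop("unknown subject id: ", subject)
  structure(
    list(subject_id = subject,
         time = cohort$data$time[i],
         hcg = cohort$data$hcg[i],
         log_hcg = cohort$data$log_hcg[i],
         disease = if (!is.null(cohort$labels)) cohort$labels[[subject]]),
    class = "trajectory")
}

#' @export
print.cohort <- function(x, ...) {
  s <- cohort_summary(x)
  cat(sprintf("<cohort> %d subjects, %d measurements (per subject: median %g, range %g-%g)\n",
              s$n_subjects, s$n_measurements,
              s$measurements_per_subject$median,
              s$measurements_per_subject$min, s$measurements_per_subject$max))
  if (!is.null(s$prevalence))
    cat(sprintf("  labeled; disease prevalence %.1f%%\n", s$prevalence))
  invisible(x)
}
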