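# Turning the classification into a diagnostic test.  Groups are ordered
# by ascending trajectory level, so the rule "the group with the highest
# trajectory level is predictive of disease" reads: group G positive,
# all other groups negative.

#' Map a fitted classification to binary disease predictions
#'
#' Subjects assigned to the top trajectory-level group are predicted
#' diseased; all others non-diseased.
#'
#' @param fit a [cem_fit()] result (groups are already ordered by
#'   trajectory level).
#' @return named logical vector of per-subject predictions.
#' @export
classify_disease <- function(fit) {
  fit$assignment == fit$spec$n_groups
}

#' Diagnostic accuracy of binary predictions
#'
#' Confusion counts and the derived metrics, all in percent:
#' sensitivity = 100 tp/(tp+fn), specificity = 100 tn/(tn+fp),
#' PPV = 100 tp/(tp+fp), NPV = 100 tn/(tn+fn), classification rate =
#' 100 (tp+tn)/N.  A metric with a zero denominator is reported as `NA`
#' (undefined), never as 0.
#'
#' @param predictions logical or 0/1 vector (positive = predicted
#'   diseased); if named, labels are aligned by name.
#' @param labels gold-standard 0/1 (or logical) disease labels.
#' @return an object of class `accuracy_summary` with fields `tp`, `fp`,
#'   `fn`, `tn`, `sensitivity`, `specificity`, `ppv`, `npv`,
#'   `classification_rate`.
#' @export
accuracy <- function(predictions, labels) {
  if (!is.null(names(predictions)) && !is.null(names(labels)))
    labels <- labels[names(predictions)]
  stopifnot(length(predictions) == length(labels), !anyNA(labels))
  pred <- as.logical(as.integer(as.logical(predictions)))
  lab <- as.logical(as.integer(as.logical(labels)))
  tp <- sum(pred & lab); fp <- sum(pred & !lab)
  fn <- sum(!pred & lab); tn <- sum(!pred & !lab)
  pct <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  structure(
    list(tp = tp, fp = fp, fn = fn, tn = tn,
         sensitivity = pct(tp, tp + fn),
         specificity = pct(tn, tn + fp),
         ppv = pct(tp, tp + fp),
         npv = pct(tn, tn + fn),
         classification_rate = pct(tp + tn, tp + fp + fn + tn)),
    class = "accuracy_summary")
}

#' @export
print.accuracy_summary <- function(x, ...) {
  f <- function(v) if (is.na(v)) "undefined" else sprintf("%.1f%%", v)
  cat(sprintf("<accuracy> tp=%d fp=%d fn=%d tn=%d\n", x$tp, x$fp, x$fn, x$tn))
  cat(sprintf("  sensitivity %s  specificity %s  PPV %s  NPV %s  classification rate %s\n",
              f(x$sensitivity), f(x$specificity), f(x$ppv), f(x$npv),
              f(x$classification_rate)))
  invisible(x)
}

# stratified fold ids: within each label stratum, shuffle then deal
# round-robin, so per-stratum fold counts differ by at most 1
.stratified_folds <- function(labels, k) {
  folds <- integer(length(labels))
  for (s in unique(labels)) {
    i <- which(labels == s)
    folds[sample(i)] <- rep_len(seq_len(k), length(i))
  }
  folds
}

#' Stratified k-fold cross-validated diagnostic accuracy
#'
#' Folds partition the subjects while preserving disease prevalence
#' (per-stratum fold counts differ by at most one).  For each fold the
#' model is fitted on the k-1 training folds, its parameters are frozen,
#' and the held-out subjects are classified by their posterior membership
#' (argmax, mixing weights fixed at the training estimates) followed by the
#' top-group disease rule.  Per-fold accuracy summaries are reported with
#' their across-fold median (even k: mean of the two middle values).
#'
#' @inheritParams m_step
#' @param k number of folds (default 4).
#' @param seed RNG seed for the fold draw (defaults to `config$seed`).
#' @return list with `folds` (named fold index per subject), `per_fold`
#'   (list of [accuracy()] summaries) and `median` (named vector of median
#'   metrics).
#' @export
stratified_kfold_cv <- function(cohort, spec, config = fit_config(), k = 4,
                                seed = config$seed) {
  if (is.null(cohort$labels)) stop("cross-validation requires disease labels")
  stopifnot(k >= 2)
  labels <- cohort$labels
  if (sum(labels == 1) < k)
    stop("a fold with zero diseased subjects: fewer diseased subjects than folds")
  if (!is.null(seed)) set.seed(seed)
  folds <- .stratified_folds(labels, k)
  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    test_ids <- cohort$subjects[folds == f]
    train_ids <- cohort$subjects[folds != f]
    train <- subset_cohort(cohort, train_ids)
    test <- subset_cohort(cohort, test_ids)
    cfg <- config
    cfg$seed <- if (!is.null(config$seed)) config$seed + 1000L * f else NULL
    fit <- cem_fit(train, spec, cfg)
    post <- .posterior_from_logf(.loglik_matrix(test, fit$structure, spec),
                                 fit$structure$pi)
    pred <- stats::setNames(c_step(post) == spec$n_groups, test_ids)
    per_fold[[f]] <- accuracy(pred, test$labels)
  }
  metrics <- c("sensitivity", "specificity", "ppv", "npv",
               "classification_rate")
  med <- vapply(metrics, function(mn)
    stats::median(vapply(per_fold, `[[`, 0, mn), na.rm = TRUE), 0)
  list(folds = stats::setNames(folds, cohort$subjects),
       per_fold = per_fold, median = med)
}
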