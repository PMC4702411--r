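test_that("the top trajectory group maps to a positive prediction", {
  fake <- structure(
    list(assignment = stats::setNames(c(1L, 4L, 2L, 4L), paste0("s", 1:4)),
         spec = model_spec("compartment", "constant", 4, "shared")),
    class = "cem_fit")
  expect_equal(classify_disease(fake),
               stats::setNames(c(FALSE, TRUE, FALSE, TRUE), paste0("s", 1:4)))
  fake2 <- structure(
    list(assignment = stats::setNames(c(1L, 2L), c("a", "b")),
         spec = model_spec("compartment", "constant", 2, "shared")),
    class = "cem_fit")
  expect_equal(unname(classify_disease(fake2)), c(FALSE, TRUE))
})

test_that("accuracy reproduces the textbook confusion-matrix formulas", {
  # random confusion inputs vs an independent formula oracle
  set.seed(14)
  for (i in 1:10) {
    n <- 200
    lab <- stats::rbinom(n, 1, 0.3)
    pred <- stats::rbinom(n, 1, 0.4)
    a <- accuracy(pred, lab)
    tp <- sum(pred == 1 & lab == 1); fp <- sum(pred == 1 & lab == 0)
    fn <- sum(pred == 0 & lab == 1); tn <- sum(pred == 0 & lab == 0)
    expect_identical(c(a$tp, a$fp, a$fn, a$tn), c(tp, fp, fn, tn))
    expect_equal(a$sensitivity, 100 * tp / (tp + fn))
    expect_equal(a$specificity, 100 * tn / (tn + fp))
    expect_equal(a$ppv, 100 * tp / (tp + fp))
    expect_equal(a$npv, 100 * tn / (tn + fn))
    expect_equal(a$classification_rate, 100 * (tp + tn) / n)
  }
  # perfect predictions
  perfect <- accuracy(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(c(perfect$sensitivity, perfect$specificity, perfect$ppv,
                 perfect$npv, perfect$classification_rate),
               rep(100, 5))
  # shuffling predictions and labels together leaves the metrics unchanged
  set.seed(15)
  o <- sample(200)
  lab <- stats::rbinom(200, 1, 0.3); pred <- stats::rbinom(200, 1, 0.4)
  expect_equal(accuracy(pred[o], lab[o]), accuracy(pred, lab))
})

test_that("undefined metrics are NA, not zero", {
  a <- accuracy(c(0, 0, 0), c(0, 1, 0))
  expect_true(is.na(a$ppv))
  expect_equal(a$sensitivity, 0)
})

test_that("stratified folds preserve prevalence to within one subject", {
  labels <- c(rep(1L, 155), rep(0L, 898))
  set.seed(6)
  folds <- kinclust:::.stratified_folds(labels, 4)
  expect_equal(sort(tabulate(folds[labels == 1], 4)), c(38, 39, 39, 39))
  expect_equal(sort(tabulate(folds[labels == 0], 4)), c(224, 224, 225, 225))
  # a partition: every subject in exactly one fold
  expect_equal(length(folds), 1053L)
  expect_true(all(folds %in% 1:4))
})

test_that("cross-validation runs end to end on a separated labeled cohort", {
  sc <- separated_scenario(60)
  coh <- simulate_cohort(sc, seed = 41)
  cv <- stratified_kfold_cv(coh, sc$spec, fast_config(seed = 41), k = 3)
  expect_length(cv$per_fold, 3)
  # folds partition the subjects and each holds some diseased subjects
  expect_length(cv$folds, 60)
  expect_true(all(cv$folds %in% 1:3))
  expect_true(all(tabulate(cv$folds[coh$labels == 1], 3) >= 1))
  expect_equal(sum(vapply(cv$per_fold, function(a) a$tp + a$fp + a$fn + a$tn, 0)),
               60)
  # strong separation: held-out accuracy is high
  expect_gte(cv$median[["classification_rate"]], 90)
})

test_that("cross-validation refuses unlabeled cohorts and empty strata", {
  sc <- separated_scenario(20)
  coh <- simulate_cohort(sc, seed = 43)
  coh$labels <- NULL
  expect_error(stratified_kfold_cv(coh, sc$spec, fast_config(), k = 4),
               "labels")
  coh2 <- simulate_cohort(sc, seed = 44)
  coh2$labels[] <- 0L
  coh2$labels[1] <- 1L
  expect_error(stratified_kfold_cv(coh2, sc$spec, fast_config(), k = 4),
               "zero diseased")
})
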