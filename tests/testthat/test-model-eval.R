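test_that("stratified folds respect class balance arithmetic", {
  lab <- c(rep(1, 8), rep(0, 27))
  f <- stratified_folds(lab, 3, seed = 1)
  expect_equal(sort(as.vector(table(f[lab == 1]))), c(2, 3, 3))
  expect_equal(as.vector(table(f[lab == 0])), c(9, 9, 9))

  f2 <- stratified_folds(lab, 3, seed = 2)
  expect_false(identical(f, f2))
  expect_equal(sort(as.vector(table(f2[lab == 1]))), c(2, 3, 3))

  expect_error(stratified_folds(rep(1, 10), 3), "single class")
  expect_error(stratified_folds(c(1, 1, 0, 0, 0, 0), 3), "fewer than k")
})

test_that("AUC matches exhaustive pair counting and is antisymmetric", {
  lab <- c(1, 1, 0, 0, 0)
  expect_equal(auc(lab, c(0.9, 0.8, 0.7, 0.6, 0.4)), 1.0)
  expect_equal(auc(lab, c(0.9, 0.5, 0.7, 0.6, 0.4)), 4 / 6)
  set.seed(21)
  for (i in 1:20) {
    labs <- rbinom(12, 1, 0.4)
    if (length(unique(labs)) < 2) next
    sc <- round(rnorm(12), 1)   # rounding forces ties
    expect_equal(auc(labs, sc), oracle_auc(labs, sc))
    expect_equal(auc(labs, sc) + auc(labs, -sc), 1)
  }
})

test_that("null scores give chance AUC and prevalence-level PRAUC", {
  set.seed(22)
  labs <- rbinom(2000, 1, 0.3)
  sc <- rnorm(2000)
  expect_equal(auc(labs, sc), 0.5, tolerance = 0.05)
  expect_equal(prauc(labs, sc), mean(labs), tolerance = 0.05)
})

test_that("fold-level average precision is biased upward at small fold sizes", {
  # at the fold sizes forced by the 8:27 split (12/3, 12/3, 11/2), average
  # precision of label-independent scores sits far above prevalence — the
  # reason the prevalence-comparable summary metric is the pooled PRAUC
  set.seed(23)
  null_ap <- function(n, k) {
    mean(replicate(2000, prauc(sample(c(rep(1, k), rep(0, n - k))),
                               seq_len(n))))
  }
  fold_bias <- mean(c(null_ap(12, 3), null_ap(12, 3), null_ap(11, 2)))
  expect_gt(fold_bias, 8 / 35 + 0.1)
  expect_equal(fold_bias, 0.38, tolerance = 0.05)
  pooled_bias <- null_ap(35, 8)
  expect_lt(abs(pooled_bias - 8 / 35), 0.1)
})

test_that("PRAUC is exact on a worked example", {
  # scores descending: labels 1,0,1,0 -> AP = (1/1)*0.5 + (2/3)*0.5
  lab <- c(1, 0, 1, 0)
  sc <- c(0.9, 0.8, 0.7, 0.6)
  expect_equal(prauc(lab, sc), 0.5 * 1 + 0.5 * 2 / 3)
})

test_that("cross-validated evaluation has the stated record structure", {
  fx <- default_cohort_fixture()
  tab <- fx$table
  ms <- model_spec("radiomic", c("original_firstorder_Minimum",
                                 "original_glszm_SizeZoneNonUniformityNormalized"),
                   seed = 5)
  cv <- evaluate_model(ms, tab, repeats = 20, k = 3)
  expect_s3_class(cv, "cv_result")
  expect_equal(nrow(cv$fold_metrics), 20 * 3)
  expect_true(all(cv$fold_metrics$auc >= 0 & cv$fold_metrics$auc <= 1))
  # fold conservation: every patient scored exactly once per repeat
  expect_true(all(colSums(!is.na(cv$oof_predictions)) == nrow(tab)))
  expect_equal(nrow(cv$roc_curve), 101L)
  expect_equal(nrow(cv$pr_curve), 101L)
  expect_error(evaluate_model(model_spec("radiomic", "not_a_feature"), tab),
               "missing from table")
})

test_that("model comparison reproduces the paired one-tailed t-test", {
  mk <- function(aucs) {
    structure(list(fold_metrics = data.frame(repeat_id = seq_along(aucs),
                                             fold = 1L, auc = aucs),
                   spec = list(seed = 1L)), class = "cv_result")
  }
  a <- mk(c(0.8, 0.9, 0.7, 0.8, 0.8))
  b <- mk(c(0.7, 0.7, 0.7, 0.7, 0.7))
  cmp <- compare_models(a, b)
  expect_equal(cmp$t, 0.1 / (sd(c(0.1, 0.2, 0, 0.1, 0.1)) / sqrt(5)),
               tolerance = 1e-12)
  expect_equal(cmp$t, 3.162278, tolerance = 1e-5)
  expect_equal(cmp$p_value, pt(cmp$t, 4, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(cmp$p_value, 0.017, tolerance = 1e-2)

  same <- compare_models(a, a)
  expect_equal(same$p_value, 0.5)

  shifted <- mk(c(0.8, 0.9, 0.7, 0.8, 0.8) + 0.1)
  expect_equal(compare_models(shifted, a)$p_value, 0)
  expect_equal(compare_models(a, shifted)$p_value, 1)

  bad <- mk(c(0.8, 0.9))
  expect_error(compare_models(a, bad), "unpaired")
})

test_that("the logit cutoff search reproduces the threshold-sweep example", {
  labs <- c(1, 1, 1, 1, 1, 0, 0, 0, 0)
  probs <- c(0.9, 0.8, 0.7, 0.2, 0.6, 0.5, 0.4, 0.3, 0.2)
  cr <- find_logit_cutoff(labs, probs, target_tpr = 0.8)
  expect_equal(cr$cutoff_prob, 0.6)
  expect_equal(cr$cutoff_logit, log(0.6 / 0.4), tolerance = 1e-12)
  expect_equal(cr$tpr, 0.8)
  expect_equal(cr$fpr, 0)
  expect_true(cr$target_reached)

  # perfectly separated: FPR 0 at TPR 1
  cr2 <- find_logit_cutoff(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1), 1.0)
  expect_equal(cr2$tpr, 1)
  expect_equal(cr2$fpr, 0)

  # all-equal probabilities: only the degenerate (1,1) operating point exists
  cr3 <- find_logit_cutoff(c(1, 0, 1, 0), rep(0.5, 4), 0.8)
  expect_equal(cr3$tpr, 1)
  expect_equal(cr3$fpr, 1)
})
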