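test_that("AUC equals the pairwise comparison statistic", {
  expect_equal(auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(auc(c(0.9, 0.8, 0.2, 0.1), c(0, 0, 1, 1)), 0.0)
  expect_equal(auc(rep(0.4, 6), c(0, 1, 1, 0, 0, 1)), 0.5)  # all ties: half credit
  set.seed(201)
  for (r in 1:50) {
    inst <- random_instance(sample(4:150, 1))
    expect_equal(auc(inst$scores, inst$labels),
                 oracle_auc(inst$scores, inst$labels), tolerance = 0,
                 info = paste("replicate", r))
  }
  expect_error(auc(c(0.1, 0.2), c(1, 1)), "both")
})

test_that("AUC is complement-symmetric and rank-invariant", {
  set.seed(31)
  s <- runif(60); y <- c(0, 1, rbinom(58, 1, 0.3))
  expect_equal(auc(s, y) + auc(1 - s, y), 1)
  expect_equal(auc(qlogis(s * 0.98 + 0.01), y), auc(s, y))  # monotone transform
  skip_if_not_installed("pROC")
  expect_equal(auc(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                              direction = "<",
                                              levels = c("0", "1")))))
})

test_that("DeLong variance matches the materialized pairwise estimator", {
  set.seed(41)
  for (r in 1:30) {
    n <- sample(10:100, 1)
    inst <- random_instance(n)
    if (sum(inst$labels) < 2 || sum(1 - inst$labels) < 2) next
    d <- suppressWarnings(delong_ci(inst$scores, inst$labels))
    expect_equal(d$variance, oracle_delong_var(inst$scores, inst$labels),
                 tolerance = 1e-12, info = paste("replicate", r))
  }
  # perfect classifier: zero variance, degenerate interval, with warning
  expect_warning(d0 <- delong_ci(c(1, 1, 0, 0), c(1, 1, 0, 0)), "degenerate")
  expect_equal(d0$variance, 0)
  skip_if_not_installed("pROC")
  s <- rnorm(150); y <- as.integer(s + rnorm(150) > 0)
  d <- delong_ci(s, y)
  ref <- pROC::ci.auc(pROC::roc(y, s, quiet = TRUE, direction = "<",
                                levels = c("0", "1")), method = "delong")
  expect_equal(c(d$ci_low, d$auc, d$ci_high), as.numeric(ref), tolerance = 1e-10)
})

test_that("bootstrap intervals behave at the edges", {
  b <- bootstrap_ci(rep(0.7, 10), mean, B = 100, seed = 1)
  expect_equal(c(b$ci_low, b$ci_high), c(0.7, 0.7))  # constant: zero width
  set.seed(3)
  s <- runif(80); y <- c(0, 1, rbinom(78, 1, 0.3))
  ba <- bootstrap_auc_ci(s, y, B = 200, seed = 2)
  expect_true(ba$ci_low >= 0 && ba$ci_high <= 1)
  expect_lte(ba$ci_low, ba$estimate)
  expect_gte(ba$ci_high, ba$estimate)
})

test_that("specificity at a sensitivity floor maximizes specificity", {
  # separable: full sensitivity with full specificity
  op <- specificity_at_sensitivity(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0), 1.0)
  expect_equal(op$specificity, 1.0)
  # both positives must be captured -> cutoff <= 0.7, specificity 1
  op2 <- specificity_at_sensitivity(c(0.9, 0.7, 0.6, 0.4), c(1, 1, 0, 0), 0.8)
  expect_lte(op2$cutoff, 0.7)
  expect_equal(op2$specificity, 1.0)
  # target 1.0 in general: cutoff at/below the minimum positive score
  set.seed(5)
  s <- runif(100); y <- c(0, 1, rbinom(98, 1, 0.3))
  op3 <- specificity_at_sensitivity(s, y, 1.0)
  expect_lte(op3$cutoff, min(s[y == 1]))
  expect_equal(op3$specificity, mean(s[y == 0] < op3$cutoff))
  expect_error(specificity_at_sensitivity(s, rep(1, 100), 0.8), "both")
})

test_that("repeated CV partitions, refits and pools per repeat", {
  co <- generate_cohort(scenario("single_view_signal", n_cases = 300), seed = 51)
  fit_fun <- function(tr, seed) {
    fit_view_classifier(tr$views$diagnoses, tr$labels, "logistic")
  }
  predict_fun <- function(m, te) predict_view(m, te$views$diagnoses)$scores
  a1 <- repeated_kfold_cv(co$dataset, fit_fun, predict_fun,
                          repeats = 3, folds = 4, seed = 9)
  expect_length(a1, 3)
  oof <- attr(a1, "oof_scores")
  expect_false(anyNA(oof))  # every case scored out-of-fold once per repeat
  a2 <- repeated_kfold_cv(co$dataset, fit_fun, predict_fun,
                          repeats = 3, folds = 4, seed = 9)
  expect_identical(as.numeric(a1), as.numeric(a2))
  expect_gt(mean(a1), 0.6)  # signal present in the diagnosis view
})

test_that("stratification failure reports the minimal viable fold count", {
  y <- c(rep(0, 50), rep(1, 3))
  expect_error(stratified_folds(y, 10, seed = 1), "at most 3 folds")
})

test_that("the superiority rule compares CI lower bound to the rival mean", {
  rep_a <- structure(list(auc = 0.75, ci_low = 0.70, ci_high = 0.80), class = "eval_report")
  rep_b <- structure(list(auc = 0.68, ci_low = 0.61, ci_high = 0.75), class = "eval_report")
  expect_true(is_superior(rep_a, rep_b))     # 0.70 > 0.68
  expect_false(is_superior(rep_b, rep_a))
  expect_false(is_superior(rep_a, 0.71))
})

test_that("evaluation reports keep their invariants in both modes", {
  set.seed(61)
  s <- runif(120); y <- c(0, 1, rbinom(118, 1, 0.3))
  r1 <- eval_report(s, y, ci_method = "delong")
  expect_true(r1$ci_low <= r1$auc && r1$auc <= r1$ci_high)
  expect_s3_class(r1$operating_points, "data.frame")
  r2 <- eval_report(per_repeat_aucs = c(0.70, 0.72, 0.71, 0.69), seed = 2)
  expect_equal(r2$auc, 0.705)
  expect_equal(length(r2$per_repeat_aucs), 4)
  expect_identical(r2$ci_method, "bootstrap")
})
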