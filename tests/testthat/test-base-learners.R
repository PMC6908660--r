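test_that("logistic inducer separates a separable toy view", {
  set.seed(1)
  toy <- toy_separable()
  clf <- fit_view_classifier(toy$view, toy$labels, "logistic")
  expect_equal(clf$train_auc, 1.0)
  pr <- predict_view(clf, toy$view)
  expect_true(all(pr$scores >= 0 & pr$scores <= 1))
})

test_that("held-out AUC is near chance under permuted labels", {
  # permutation-null simulation: no inducer should find signal in noise
  set.seed(7)
  reps <- 50
  for (ind in c("logistic", "svm")) {
    aucs <- vapply(seq_len(reps), function(r) {
      n <- 160
      x <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("f", 1:3)))
      y <- sample(rep(0:1, each = n / 2))
      tr <- seq_len(n / 2)
      clf <- fit_view_classifier(view_matrix("v", x[tr, ], rep(TRUE, n / 2)),
                                 y[tr], ind)
      sc <- predict_view(clf, view_matrix("v", x[-tr, ], rep(TRUE, n / 2)))
      auc(sc$scores, y[-tr])
    }, 0)
    expect_lt(abs(mean(aucs) - 0.5), 0.1)
  }
})

test_that("constant-feature views degrade to a warned constant score", {
  v <- view_matrix("flat", cbind(f = rep(2, 30)), rep(TRUE, 30))
  y <- rep(0:1, 15)
  expect_warning(clf <- fit_view_classifier(v, y, "logistic"), "constant")
  expect_equal(unique(predict_view(clf, v)$scores), 0.5)
})

test_that("fitting refuses single-class or empty available rows", {
  v <- view_matrix("v", cbind(f = rnorm(10)), rep(TRUE, 10))
  expect_error(fit_view_classifier(v, rep(1, 10), "logistic"), "drop this view")
  v0 <- view_matrix("v", cbind(f = rnorm(10)), rep(FALSE, 10))
  expect_error(fit_view_classifier(v0, rep(0:1, 5), "logistic"), "no available rows")
})

test_that("unavailable rows never influence fitting", {
  set.seed(3)
  n <- 80
  x <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("a", "b")))
  y <- as.integer(x[, 1] + rnorm(n, 0, 0.5) > 0)
  avail <- c(rep(TRUE, 50), rep(FALSE, 30))
  # poison the masked rows: they must not matter
  x_poisoned <- x; x_poisoned[!avail, ] <- 1e6
  for (ind in c("logistic", "svm", "svr")) {
    full <- fit_view_classifier(view_matrix("v", x_poisoned, avail), y, ind)
    only <- fit_view_classifier(view_matrix("v", x[avail, , drop = FALSE],
                                            rep(TRUE, 50)), y[avail], ind)
    expect_equal(full$params, only$params, info = ind)
  }
})

test_that("prediction is deterministic and flags unavailable rows", {
  set.seed(5)
  toy <- toy_separable()
  clf <- fit_view_classifier(toy$view, toy$labels, "svm")
  pr1 <- predict_view(clf, toy$view)
  pr2 <- predict_view(clf, toy$view)
  expect_identical(pr1$scores, pr2$scores)
  # all rows unavailable -> no scores, full missing mask
  v_off <- view_matrix("toy", toy$view$values, rep(FALSE, 40))
  pr3 <- predict_view(clf, v_off)
  expect_true(all(is.na(pr3$scores)))
  expect_true(all(!pr3$available))
  # feature mismatch errors name the offending columns
  v_bad <- view_matrix("toy", cbind(f1 = rnorm(5), zz = rnorm(5)), rep(TRUE, 5))
  expect_error(predict_view(clf, v_bad), "zz")
})

test_that("logistic scores are monotone in positively weighted features", {
  set.seed(11)
  n <- 300
  x <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("up", "noise")))
  y <- as.integer(x[, 1] + rnorm(n, 0, 0.3) > 0)
  clf <- fit_view_classifier(view_matrix("v", x, rep(TRUE, n)), y, "logistic")
  expect_gt(clf$params$coefficients[["up"]], 0)
  base <- predict_view(clf, view_matrix("v", cbind(up = 0, noise = 0), TRUE))$scores
  bumped <- predict_view(clf, view_matrix("v", cbind(up = 1, noise = 0), TRUE))$scores
  expect_gt(bumped, base)
})

test_that("Platt calibration preserves the ranking of decision values", {
  set.seed(13)
  n <- 200
  x <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("f", 1:3)))
  y <- as.integer(x[, 1] - x[, 2] + rnorm(n, 0, 0.8) > 0)
  clf <- fit_view_classifier(view_matrix("v", x, rep(TRUE, n)), y, "svm")
  dec <- melmv:::svm_decision(clf$params, x)
  cal <- predict_view(clf, view_matrix("v", x, rep(TRUE, n)))$scores
  expect_equal(auc(cal, y), auc(dec, y))
  expect_true(all(cal >= 0 & cal <= 1))
})

test_that("classifiers serialize to JSON and back exactly", {
  set.seed(17)
  n <- 120
  x <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("f", 1:3)))
  y <- as.integer(x[, 1] + rnorm(n) > 0)
  v <- view_matrix("v", x, rep(TRUE, n))
  for (spec in list(list("logistic", "linear"), list("svm", "linear"),
                    list("svm", "radial"), list("svr", "linear"))) {
    clf <- fit_view_classifier(v, y, spec[[1]],
                               learner_control(svm_kernel = spec[[2]]))
    clf <- calibrate_threshold(clf, v, y)
    path <- withr::local_tempfile(fileext = ".json")
    save_classifier(clf, path)
    back <- load_classifier(path)
    expect_identical(predict_view(back, v)$scores, predict_view(clf, v)$scores,
                     info = paste(spec[[1]], spec[[2]]))
    expect_identical(back$threshold, clf$threshold)
  }
})
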