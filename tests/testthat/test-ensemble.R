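test_that("wrapper selection recovers an informative column among noise", {
  hits <- 0L
  for (r in 1:50) {
    meta <- toy_meta(n = 200, n_noise = 3, seed = 100 + r)
    sel <- wrapper_select(meta, folds = 5, seed = r, search = "exhaustive")
    hits <- hits + ("signal" %in% sel$selected)
  }
  expect_gte(hits, 48L)  # >= 95% recovery
})

test_that("a single candidate is always selected", {
  meta <- toy_meta(n = 100, n_noise = 0)
  sel <- wrapper_select(meta, folds = 4, seed = 1)
  expect_identical(sel$selected, "signal")
})

test_that("exhaustive and greedy agree when one subset dominates", {
  meta <- toy_meta(n = 300, n_noise = 3, seed = 5)
  ex <- wrapper_select(meta, folds = 5, seed = 2, search = "exhaustive")
  gr <- wrapper_select(meta, folds = 5, seed = 2, search = "greedy")
  expect_true("signal" %in% ex$selected)
  expect_true("signal" %in% gr$selected)
})

test_that("ties break toward the smaller subset", {
  meta <- toy_meta(n = 150, n_noise = 0, seed = 3)
  meta$table$copy <- meta$table$signal  # duplicate carries no extra information
  sel <- wrapper_select(meta, folds = 5, seed = 4, search = "exhaustive")
  expect_identical(sel$selected, "signal")
})

test_that("the selected subset scores at least as well as every singleton", {
  meta <- toy_meta(n = 250, n_noise = 4, seed = 8)
  for (mode in c("exhaustive", "greedy")) {
    sel <- wrapper_select(meta, folds = 5, seed = 6, search = mode)
    singles <- sel$search_log[!grepl("\\+", sel$search_log$subset), ]
    expect_gte(sel$cv_auc, max(singles$cv_auc))
  }
})

test_that("pure-noise candidates trigger the single-column fallback", {
  set.seed(9)
  meta <- toy_meta(n = 120, n_noise = 2)
  meta$table$signal <- NULL
  meta$columns <- meta$columns[-1, ]
  expect_warning(sel <- wrapper_select(meta, folds = 4, seed = 2,
                                       search = "exhaustive"),
                 "single best column")
  expect_length(sel$selected, 1L)
})

test_that("the meta-learner refits deterministically with sane coefficients", {
  meta <- toy_meta(n = 300, n_noise = 1, seed = 12)
  m1 <- fit_meta(meta, c("signal", "noise1"))
  m2 <- fit_meta(meta, c("signal", "noise1"))
  expect_identical(m1$meta_coefficients, m2$meta_coefficients)
  # a label-correlated column gets a positive weight
  expect_gt(m1$meta_coefficients[["signal"]], 0)
  expect_error(fit_meta(meta, "nonexistent"), "nonexistent")
})

test_that("perfect separation falls back to a ridge-penalized meta-fit", {
  y <- rep(0:1, each = 25)
  meta <- structure(list(table = data.frame(perfect = y), labels = y,
                         case_ids = as.character(1:50),
                         columns = data.frame(name = "perfect", view = NA,
                                              inducer = NA, kind = "score"),
                         flag_views = character(0)),
                    class = "meta_features")
  expect_warning(m <- fit_meta(meta, "perfect"), "separation")
  expect_true(all(is.finite(m$meta_coefficients)))
})

test_that("the severity index is the logistic transform of the meta-predictor", {
  model <- structure(list(selected_columns = c("a", "b"),
                          meta_coefficients = c(`(Intercept)` = 0, a = 0, b = 0)),
                     class = "ensemble_model")
  # all-zero coefficients -> 0.5 everywhere
  expect_equal(severity_index(model, data.frame(a = c(-3, 9), b = c(0, 2))),
               c(0.5, 0.5))
  model$meta_coefficients <- c(`(Intercept)` = 0, a = 1, b = -0.5)
  rows <- data.frame(a = c(0, 1, 2), b = c(1, 1, 1))
  batch <- severity_index(model, rows)
  expect_true(all(diff(batch) > 0))  # monotone in the positive column
  rowwise <- vapply(1:3, function(i) severity_index(model, rows[i, ]), 0)
  expect_identical(batch, rowwise)
  expect_error(severity_index(model, data.frame(a = 1)), "\\bb\\b")
})

test_that("the full pipeline is reproducible end to end under one seed", {
  co <- generate_cohort(scenario("all_view_signal", n_cases = 400), seed = 31)
  cfg <- melmv_config(search = "greedy", selection_folds = 4)
  suppressWarnings({
    m1 <- fit_melmv(co$dataset, cfg, seed = 7)
    m2 <- fit_melmv(co$dataset, cfg, seed = 7)
  })
  expect_identical(m1$ensemble$selected_columns, m2$ensemble$selected_columns)
  expect_identical(predict(m1, co$dataset), predict(m2, co$dataset))
})

test_that("fitted ensembles serialize to JSON and score identically", {
  co <- generate_cohort(scenario("all_view_signal", n_cases = 400), seed = 33)
  cfg <- melmv_config(search = "greedy", selection_folds = 4)
  suppressWarnings(m <- fit_melmv(co$dataset, cfg, seed = 7))
  path <- withr::local_tempfile(fileext = ".json")
  save_melmv_model(m, path)
  back <- load_melmv_model(path)
  expect_identical(predict(back, co$dataset), predict(m, co$dataset))
})
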