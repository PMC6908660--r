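#' Baseline comparators
#'
#' The comparison roster mirrors the study design: single-model baselines fit
#' one global logistic regression or SVM on the concatenation of all views
#' after chained-equation imputation of the missing entries; a random forest
#' replaces the logistic meta-learner on exactly the same meta-features the
#' ensemble sees; and two simple ensembles (all candidates without selection;
#' a combiner of the two single-view models) complete the table.
#'
#' @name baselines
NULL

#' The baseline comparator kinds
#' @export
BASELINE_KINDS <- c("single_lg", "single_svm", "rf_meta", "ensemble_all",
                    "ensemble_single_lg_svm")

#' Concatenate all views into a single feature matrix
#'
#' Column-wise concatenation with view-prefixed names; entries of unavailable
#' views become `NA`, awaiting imputation.
#'
#' @param dataset a [multiview_dataset()].
#' @return numeric matrix with missing entries.
#' @export
concat_views <- function(dataset) {
  blocks <- lapply(dataset$views, function(v) {
    m <- v$values
    colnames(m) <- paste(v$view_name, colnames(m), sep = ".")
    m
  })
  do.call(cbind, unname(blocks))
}

#' Chained-equation imputation of a matrix with missing entries
#'
#' Iterative per-column conditional imputation: each incomplete column is
#' regressed on a pre-screened predictor set (linear model for numeric
#' columns, logistic for binary ones), and its missing entries are drawn from
#' the fitted conditional distribution; the cycle runs `iterations` times.
#' Draws are stochastic by design — different seeds give different
#' completions. Predictors per column are pre-screened to the
#' `max_predictors` columns with largest absolute correlation, which keeps
#' the procedure tractable on the several-hundred-column concatenated matrix.
#'
#' The fitted per-column models of the final cycle are attached as attribute
#' `"models"` so held-out data can be imputed with training-fitted models only
#' (see [apply_imputation()]).
#'
#' @param x numeric matrix with `NA` for missing entries; no column may be
#'   entirely missing.
#' @param iterations number of cycles (default 10).
#' @param seed integer seed.
#' @param max_predictors predictor-screening cap per column.
#' @return the completed matrix, with imputation models attached.
#' @export
chained_equation_impute <- function(x, iterations = 10, seed = 1,
                                    max_predictors = 30) {
  x <- as.matrix(x)
  n_miss <- colSums(is.na(x))
  if (any(n_miss == nrow(x))) {
    stop("column(s) entirely missing: ",
         paste(colnames(x)[n_miss == nrow(x)], collapse = ", "), call. = FALSE)
  }
  incomplete <- which(n_miss > 0L)
  col_means <- vapply(seq_len(ncol(x)), function(j) mean(x[, j], na.rm = TRUE), 0)
  if (!length(incomplete)) {
    attr(x, "models") <- list(columns = integer(0), init_means = col_means,
                              iterations = iterations, specs = list())
    return(x)
  }
  set.seed(seed)
  miss <- is.na(x)
  xc <- x
  for (j in seq_len(ncol(x))) xc[miss[, j], j] <- col_means[j]

  incomplete <- incomplete[order(n_miss[incomplete])]
  specs <- vector("list", length(incomplete))
  names(specs) <- colnames(x)[incomplete]
  # predictor screening on the mean-initialized matrix
  sds <- apply(xc, 2, stats::sd)
  for (ii in seq_along(incomplete)) {
    j <- incomplete[ii]
    others <- setdiff(which(sds > 0), j)
    if (length(others)) {
      cors <- abs(suppressWarnings(stats::cor(xc[, j], xc[, others])))
      cors[!is.finite(cors)] <- 0
      preds <- others[order(cors, decreasing = TRUE)][
        seq_len(min(max_predictors, length(others)))]
    } else preds <- integer(0)
    obs <- x[!miss[, j], j]
    # cap predictors by observed support and squeeze draws into the observed
    # range: columns observed on few rows (bone density) destabilize the
    # cycle otherwise
    if (length(preds) > max(1L, floor(length(obs) / 3))) {
      preds <- preds[seq_len(max(1L, floor(length(obs) / 3)))]
    }
    specs[[ii]] <- list(col = j, preds = preds,
                        binary = all(obs %in% c(0, 1)),
                        lo = min(obs), hi = max(obs),
                        marg_mean = mean(obs), marg_sd = stats::sd(obs))
  }

  for (it in seq_len(iterations)) {
    for (ii in seq_along(incomplete)) {
      sp <- specs[[ii]]
      j <- sp$col
      mj <- miss[, j]
      sp <- fit_impute_model(sp, xc, !mj, x[!mj, j])
      xc[mj, j] <- draw_impute(sp, xc[mj, sp$preds, drop = FALSE])
      specs[[ii]] <- sp
    }
  }
  attr(xc, "models") <- list(columns = incomplete, init_means = col_means,
                             iterations = iterations, specs = specs)
  xc
}

fit_impute_model <- function(sp, xc, obs_rows, y_obs) {
  if (!length(sp$preds) || (sp$binary && length(unique(y_obs)) < 2L) ||
      (!sp$binary && stats::sd(y_obs) == 0)) {
    sp$coefs <- NULL
    return(sp)
  }
  xm <- cbind(1, xc[obs_rows, sp$preds, drop = FALSE])
  if (sp$binary) {
    cf <- suppressWarnings(
      stats::glm.fit(xm, y_obs, family = stats::binomial())$coefficients)
  } else {
    fit <- stats::lm.fit(xm, y_obs)
    cf <- fit$coefficients
    sp$sigma <- sqrt(sum(fit$residuals^2) /
                       max(1L, length(y_obs) - sum(is.finite(cf))))
  }
  cf[!is.finite(cf)] <- 0
  sp$coefs <- cf
  sp
}

draw_impute <- function(sp, xmiss) {
  k <- nrow(xmiss)
  if (is.null(sp$coefs)) {
    if (sp$binary) return(stats::rbinom(k, 1, sp$marg_mean))
    return(pmin(sp$hi, pmax(sp$lo,
      stats::rnorm(k, sp$marg_mean, max(sp$marg_sd, 0)))))
  }
  eta <- as.numeric(cbind(1, xmiss) %*% sp$coefs)
  if (sp$binary) stats::rbinom(k, 1, sigmoid(eta))
  else pmin(sp$hi, pmax(sp$lo, stats::rnorm(k, eta, sp$sigma)))
}

#' Impute held-out data with training-fitted models
#'
#' Missing entries are initialized at the training column means and cycled
#' through the stored per-column conditional models; no held-out information
#' enters the imputation models.
#'
#' @param models the `"models"` attribute of [chained_equation_impute()].
#' @param x held-out matrix with `NA` entries (same columns as training).
#' @param seed integer seed for the conditional draws.
#' @return the completed matrix.
#' @export
apply_imputation <- function(models, x, seed = 1) {
  x <- as.matrix(x)
  miss <- is.na(x)
  if (!any(miss)) return(x)
  set.seed(seed)
  for (j in seq_len(ncol(x))) x[miss[, j], j] <- models$init_means[j]
  for (it in seq_len(models$iterations)) {
    for (sp in models$specs) {
      mj <- miss[, sp$col]
      if (any(mj)) x[mj, sp$col] <- draw_impute(sp, x[mj, sp$preds, drop = FALSE])
    }
  }
  x
}

#' Fit a baseline comparator
#'
#' @param dataset training [multiview_dataset()].
#' @param kind one of `"single_lg"`, `"single_svm"`, `"rf_meta"`,
#'   `"ensemble_all"`, `"ensemble_single_lg_svm"`.
#' @param config a [melmv_config()].
#' @param seed integer seed (imputation draws, forest).
#' @param stage_one optional precomputed [fit_stage_one()] classifiers (shared
#'   with the ensemble for paired comparisons).
#' @param imputed optional precomputed imputed concatenation (shared between
#'   the two single-view baselines, as in the study design).
#' @return an object of class `baseline_model`.
#' @export
fit_baseline <- function(dataset, kind = BASELINE_KINDS, config = melmv_config(),
                         seed = 1, stage_one = NULL, imputed = NULL) {
  kind <- match.arg(kind)
  labels <- check_labels(dataset$labels)

  if (kind %in% c("single_lg", "single_svm", "ensemble_single_lg_svm")) {
    if (is.null(imputed)) {
      imputed <- chained_equation_impute(
        concat_views(dataset), iterations = config$imputation_iterations,
        seed = derive_seed(seed, "impute"),
        max_predictors = config$imputation_max_predictors)
    }
    imp_models <- attr(imputed, "models")
    make_single <- function(inducer) {
      vw <- view_matrix("concat", imputed, rep(TRUE, nrow(imputed)))
      fit_view_classifier(vw, labels, inducer, config$learner)
    }
    if (kind == "ensemble_single_lg_svm") {
      lg <- make_single("logistic")
      sv <- make_single("svm")
      vw <- view_matrix("concat", imputed, rep(TRUE, nrow(imputed)))
      sc <- cbind(lg = predict_view(lg, vw)$scores,
                  svm = predict_view(sv, vw)$scores)
      comb <- logistic_fit(sc, labels)
      model <- list(lg = lg, svm = sv, combiner = comb)
    } else {
      model <- make_single(if (kind == "single_lg") "logistic" else "svm")
    }
    return(structure(list(kind = kind, model = model, imputation = imp_models,
                          config = config, seed = seed),
                     class = "baseline_model"))
  }

  if (is.null(stage_one)) stage_one <- fit_stage_one(dataset, config)
  meta <- build_meta_features(dataset, stage_one)

  if (kind == "ensemble_all") {
    ens <- fit_meta(meta, colnames(meta$table))
    model <- ens
  } else { # rf_meta
    model <- fit_rf_meta(meta, trees = config$rf_trees,
                         seed = derive_seed(seed, "rf"))
  }
  structure(list(kind = kind, model = model, stage_one = stage_one,
                 flag_views = meta$flag_views, config = config, seed = seed),
            class = "baseline_model")
}

#' Random-forest meta-learner
#'
#' A random forest on exactly the candidate meta-features the ensemble sees
#' (classifier scores + missing flags). The variables-per-split parameter is
#' chosen by stratified cross-validated AUC over a small grid.
#'
#' @param meta a `meta_features` table.
#' @param trees forest size.
#' @param seed integer seed.
#' @param folds tuning-CV folds.
#' @return a fitted `randomForest` object with the chosen `mtry`.
#' @export
fit_rf_meta <- function(meta, trees = 500, seed = 1, folds = 5) {
  x <- as.data.frame(meta$table)
  y <- factor(check_labels(meta$labels), levels = c(0, 1))
  p <- ncol(x)
  grid <- sort(unique(pmax(1L, c(1L, floor(sqrt(p)), floor(p / 2)))))
  fold <- stratified_folds(meta$labels, folds, derive_seed(seed, "rf-tune"))
  cv_auc <- vapply(grid, function(m) {
    oof <- numeric(nrow(x))
    for (k in seq_len(folds)) {
      set.seed(derive_seed(seed, paste0("rf-", m, "-", k)))
      rf <- randomForest::randomForest(x[fold != k, , drop = FALSE],
                                       y[fold != k], ntree = trees, mtry = m)
      oof[fold == k] <- stats::predict(rf, x[fold == k, , drop = FALSE],
                                       type = "prob")[, "1"]
    }
    auc(oof, meta$labels)
  }, 0)
  best <- grid[which.max(cv_auc)]
  set.seed(derive_seed(seed, "rf-final"))
  rf <- randomForest::randomForest(x, y, ntree = trees, mtry = best)
  attr(rf, "tuning") <- data.frame(mtry = grid, cv_auc = cv_auc)
  rf
}

#' @export
print.baseline_model <- function(x, ...) {
  cat(sprintf("<baseline_model: %s>\n", x$kind))
  invisible(x)
}

#' Score new cases with a baseline model
#'
#' @param object a [fit_baseline()] model.
#' @param newdata a [multiview_dataset()].
#' @param ... unused.
#' @return numeric severity scores in \[0, 1\].
#' @export
predict.baseline_model <- function(object, newdata, ...) {
  if (object$kind %in% c("single_lg", "single_svm", "ensemble_single_lg_svm")) {
    xc <- concat_views(newdata)
    xi <- apply_imputation(object$imputation, xc,
                           seed = derive_seed(object$seed, "impute-new"))
    vw <- view_matrix("concat", xi, rep(TRUE, nrow(xi)))
    if (object$kind == "ensemble_single_lg_svm") {
      sc <- cbind(lg = predict_view(object$model$lg, vw)$scores,
                  svm = predict_view(object$model$svm, vw)$scores)
      return(logistic_predict(object$model$combiner, sc))
    }
    return(predict_view(object$model, vw)$scores)
  }
  meta <- build_meta_features(newdata, object$stage_one,
                              flag_views = object$flag_views)
  if (object$kind == "ensemble_all") {
    return(severity_index(object$model, meta))
  }
  stats::predict(object$model, as.data.frame(meta$table), type = "prob")[, "1"]
}

#' Fit the ensemble and a roster of baselines on shared computations
#'
#' Stage-one classifiers and the imputed concatenation are computed once and
#' shared across the models that need them, exactly as in the study design
#' ("with the same classifiers and missing flags as features"; one imputation
#' feeding both single models).
#'
#' @param dataset training [multiview_dataset()].
#' @param kinds character vector from `"melmv"` plus [BASELINE_KINDS].
#' @param config a [melmv_config()].
#' @param seed integer seed.
#' @return named list of fitted models.
#' @export
fit_model_roster <- function(dataset, kinds, config = melmv_config(), seed = 1) {
  kinds <- match.arg(kinds, c("melmv", BASELINE_KINDS), several.ok = TRUE)
  stage_one <- NULL
  imputed <- NULL
  if (any(kinds %in% c("melmv", "rf_meta", "ensemble_all"))) {
    stage_one <- fit_stage_one(dataset, config)
  }
  if (any(kinds %in% c("single_lg", "single_svm", "ensemble_single_lg_svm"))) {
    imputed <- chained_equation_impute(
      concat_views(dataset), iterations = config$imputation_iterations,
      seed = derive_seed(seed, "impute"),
      max_predictors = config$imputation_max_predictors)
  }
  models <- list()
  for (k in kinds) {
    models[[k]] <- if (k == "melmv") {
      meta <- build_meta_features(dataset, stage_one)
      sel <- wrapper_select(meta, folds = config$selection_folds,
                            seed = derive_seed(seed, "select"),
                            search = config$search,
                            exhaustive_limit = config$exhaustive_limit,
                            improve_tol = config$improve_tol)
      structure(list(classifiers = stage_one, flag_views = meta$flag_views,
                     ensemble = fit_meta(meta, sel), config = config,
                     seed = seed),
                class = "melmv_model")
    } else {
      fit_baseline(dataset, k, config, seed, stage_one = stage_one,
                   imputed = imputed)
    }
  }
  models
}

#' Held-out comparison of the ensemble against the baselines
#'
#' Fits all requested models on `train` (sharing stage-one classifiers and
#' imputation) and evaluates each on `test`.
#'
#' @param train,test [multiview_dataset()] splits.
#' @param kinds models to compare (default: the ensemble and all baselines).
#' @param config a [melmv_config()].
#' @param seed integer seed.
#' @param ci CI method for the per-model report (`"delong"` or `"none"`).
#' @return data.frame with one row per model (kind, auc, ci bounds), scores
#'   attached as attribute `"scores"`.
#' @export
compare_holdout <- function(train, test, kinds = c("melmv", BASELINE_KINDS),
                            config = melmv_config(), seed = 1,
                            ci = c("delong", "none")) {
  ci <- match.arg(ci)
  models <- fit_model_roster(train, kinds, config, seed)
  scores <- vapply(models, function(m) predict(m, test), numeric(length(test$labels)))
  rows <- lapply(kinds, function(k) {
    a <- auc(scores[, k], test$labels)
    if (ci == "delong" && sum(test$labels == 1) >= 2 && sum(test$labels == 0) >= 2) {
      d <- delong_ci(scores[, k], test$labels)
      data.frame(kind = k, auc = a, ci_low = d$ci_low, ci_high = d$ci_high)
    } else {
      data.frame(kind = k, auc = a, ci_low = NA_real_, ci_high = NA_real_)
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "scores") <- scores
  out
}

#' Repeated-CV comparison under shared partitions
#'
#' All models are evaluated under identical outer CV partitions (paired
#' comparison); within each training fold the shared stage-one classifiers /
#' imputation are refit once and every model is derived from them.
#'
#' @inheritParams compare_holdout
#' @param dataset a [multiview_dataset()].
#' @param repeats,folds outer CV scheme.
#' @return matrix of per-repeat pooled out-of-fold AUCs (repeats x kinds).
#' @export
cv_compare <- function(dataset, kinds = c("melmv", BASELINE_KINDS),
                       config = melmv_config(), repeats = 10, folds = 10,
                       seed = 1) {
  labels <- check_labels(dataset$labels)
  n <- length(labels)
  aucs <- matrix(NA_real_, repeats, length(kinds),
                 dimnames = list(NULL, kinds))
  for (r in seq_len(repeats)) {
    fold <- stratified_folds(labels, folds, derive_seed(seed, paste0("cmp-rep", r)))
    oof <- matrix(NA_real_, n, length(kinds), dimnames = list(NULL, kinds))
    for (k in seq_len(folds)) {
      tr <- subset_dataset(dataset, fold != k)
      te <- subset_dataset(dataset, fold == k)
      models <- fit_model_roster(tr, kinds, config,
                                 derive_seed(seed, paste0("cmp-fit", r, "-", k)))
      for (kind in kinds) oof[fold == k, kind] <- predict(models[[kind]], te)
    }
    aucs[r, ] <- apply(oof, 2, auc, labels = labels)
  }
  aucs
}
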