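#' Wrapper ensemble selection and the logistic meta-learner
#'
#' Rather than combining every stage-one output, the ensemble selects the
#' subset of meta-features (classifier scores and missing flags) that
#' maximizes the cross-validated AUC of a logistic meta-learner — a wrapper
#' search, exhaustive when the candidate roster is small and greedy-forward
#' otherwise. The selected subset is then refit on the full training table;
#' its sigmoid output is the severity index.
#'
#' @name ensemble-selection
NULL

#' Pipeline configuration
#'
#' @param inducers named list mapping each view to its base-inducer grid.
#'   Defaults follow the canonical design: logistic + SVM for demographics,
#'   diagnoses and procedures; logistic + SVR for the two low-dimensional
#'   bone-density views.
#' @param search `"auto"` (exhaustive up to `exhaustive_limit` candidates,
#'   greedy beyond), `"exhaustive"` or `"greedy"`.
#' @param selection_folds folds of the selection-scoring cross-validation.
#' @param exhaustive_limit largest candidate count searched exhaustively.
#' @param improve_tol greedy search stops when no addition improves the CV
#'   AUC by more than this.
#' @param learner a [learner_control()].
#' @param imputation_iterations,imputation_max_predictors chained-equation
#'   settings used by the single-view baselines.
#' @param rf_trees random-forest size for the forest meta-learner baseline.
#' @return a list of class `melmv_config`.
#' @export
melmv_config <- function(inducers = list(demographics = c("logistic", "svm"),
                                         diagnoses = c("logistic", "svm"),
                                         procedures = c("logistic", "svm"),
                                         bd_forearm = c("logistic", "svr"),
                                         bd_dual_femur = c("logistic", "svr")),
                         search = c("auto", "exhaustive", "greedy"),
                         selection_folds = 10, exhaustive_limit = 15,
                         improve_tol = 1e-4,
                         learner = learner_control(),
                         imputation_iterations = 10,
                         imputation_max_predictors = 30,
                         rf_trees = 500) {
  structure(list(inducers = inducers, search = match.arg(search),
                 selection_folds = selection_folds,
                 exhaustive_limit = exhaustive_limit,
                 improve_tol = improve_tol, learner = learner,
                 imputation_iterations = imputation_iterations,
                 imputation_max_predictors = imputation_max_predictors,
                 rf_trees = rf_trees),
            class = "melmv_config")
}

# Pooled out-of-fold AUC of a logistic model on a column subset.
subset_cv_auc <- function(x, y, cols, fold) {
  oof <- numeric(length(y))
  for (k in sort(unique(fold))) {
    tr <- fold != k
    cf <- logistic_fit(x[tr, cols, drop = FALSE], y[tr])
    oof[!tr] <- logistic_predict(cf, x[!tr, cols, drop = FALSE])
  }
  auc(oof, y)
}

#' Wrapper selection of the meta-feature subset
#'
#' Scores every candidate subset by the pooled out-of-fold AUC of a logistic
#' meta-learner under one stratified k-fold partition (shared across subsets,
#' so the comparison is paired). Ties are broken toward the smaller subset,
#' then lexicographically by column order. If no subset scores above 0.5 the
#' single best column is returned with a warning (the selection is never
#' empty).
#'
#' @param meta a [build_meta_features()] table.
#' @param folds selection-CV folds.
#' @param seed integer seed for the fold partition.
#' @param search `"auto"`, `"exhaustive"` or `"greedy"` (forward).
#' @param exhaustive_limit candidate count above which `"auto"` switches to
#'   greedy search.
#' @param improve_tol greedy stopping tolerance on the CV-AUC gain.
#' @return an object of class `wrapper_selection` with `selected`
#'   (column names), `cv_auc`, and `search_log` (every evaluated subset with
#'   its score).
#' @export
wrapper_select <- function(meta, folds = 10, seed = 1,
                           search = c("auto", "exhaustive", "greedy"),
                           exhaustive_limit = 15, improve_tol = 1e-4) {
  search <- match.arg(search)
  x <- as.matrix(meta$table)
  y <- check_labels(meta$labels)
  cand <- colnames(x)
  p <- length(cand)
  stopifnot(p >= 1L)
  fold <- stratified_folds(y, folds, seed)
  if (search == "auto") {
    search <- if (p <= exhaustive_limit) "exhaustive" else "greedy"
  }

  log_subsets <- character(0)
  log_aucs <- numeric(0)

  if (search == "exhaustive") {
    best_auc <- -Inf; best_cols <- NULL
    sing_auc <- rep(-Inf, p)
    for (mask in seq_len(2^p - 1L)) {
      cols <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(p) - 1L)) != 0L)
      a <- subset_cv_auc(x, y, cols, fold)
      log_subsets <- c(log_subsets, paste(cand[cols], collapse = "+"))
      log_aucs <- c(log_aucs, a)
      if (length(cols) == 1L) sing_auc[cols] <- a
      if (is.null(best_cols) || a > best_auc ||
          (a == best_auc && (length(cols) < length(best_cols) ||
             (length(cols) == length(best_cols) && lex_less(cols, best_cols))))) {
        best_auc <- a; best_cols <- cols
      }
    }
  } else {
    selected <- integer(0)
    best_auc <- -Inf
    sing_auc <- rep(-Inf, p)
    repeat {
      remaining <- setdiff(seq_len(p), selected)
      if (!length(remaining)) break
      round_auc <- vapply(remaining, function(j) {
        a <- subset_cv_auc(x, y, c(selected, j), fold)
        a
      }, 0)
      log_subsets <- c(log_subsets, vapply(remaining, function(j) {
        paste(cand[c(selected, j)], collapse = "+")
      }, ""))
      log_aucs <- c(log_aucs, round_auc)
      if (!length(selected)) sing_auc <- replace(sing_auc, remaining, round_auc)
      jbest <- remaining[which.max(round_auc)]
      gain <- max(round_auc) - best_auc
      if (!length(selected) || gain > improve_tol) {
        selected <- c(selected, jbest)
        best_auc <- max(round_auc)
      } else break
    }
    best_cols <- sort(selected)
  }

  if (best_auc <= 0.5) {
    warning("no subset beats AUC 0.5; returning the single best column",
            call. = FALSE)
    best_cols <- which.max(sing_auc)
    best_auc <- sing_auc[best_cols]
  }
  structure(
    list(selected = cand[sort(best_cols)], cv_auc = best_auc,
         search = search, folds = folds, seed = seed,
         search_log = data.frame(subset = log_subsets, cv_auc = log_aucs,
                                 stringsAsFactors = FALSE)),
    class = "wrapper_selection"
  )
}

# TRUE when index set a precedes b lexicographically (both sorted, same length).
lex_less <- function(a, b) {
  d <- which(a != b)
  length(d) > 0L && a[d[1L]] < b[d[1L]]
}

#' Fit the logistic meta-learner on a selected subset
#'
#' @param meta a `meta_features` table.
#' @param selection a [wrapper_select()] result, or a character vector of
#'   column names.
#' @return an object of class `ensemble_model` with the selected columns,
#'   meta-coefficients (intercept first), the selection CV AUC and the search
#'   log. Perfect separation falls back to a ridge-penalized fit with a
#'   warning.
#' @export
fit_meta <- function(meta, selection) {
  if (inherits(selection, "wrapper_selection")) {
    selected <- selection$selected
    cv_auc <- selection$cv_auc
    search_log <- selection$search_log
  } else {
    selected <- selection
    cv_auc <- NA_real_
    search_log <- NULL
  }
  missing_cols <- setdiff(selected, colnames(meta$table))
  if (length(missing_cols)) {
    stop("selected column(s) not in meta table: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- as.matrix(meta$table[, selected, drop = FALSE])
  y <- check_labels(meta$labels)
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(cbind(1, x), y, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities|did not converge", conditionMessage(w))) {
        separated <<- TRUE
      }
      invokeRestart("muffleWarning")
    }
  )
  cf <- fit$coefficients
  # separation can also converge quietly to boundary fits
  if (any(fit$fitted.values < 1e-10 | fit$fitted.values > 1 - 1e-10)) {
    separated <- TRUE
  }
  if (separated || any(!is.finite(cf))) {
    warning("perfect separation in meta-fit; falling back to ridge penalty",
            call. = FALSE)
    xr <- if (ncol(x) == 1L) cbind(x, `.dummy` = 0) else x
    fit <- glmnet::glmnet(xr, y, family = "binomial", alpha = 0,
                          lambda = 0.01, standardize = FALSE)
    cf <- c(as.numeric(fit$a0), as.numeric(fit$beta[seq_len(ncol(x)), 1L]))
  }
  names(cf) <- c("(Intercept)", selected)
  structure(
    list(selected_columns = selected, meta_coefficients = cf,
         selection_cv_auc = cv_auc, search_log = search_log),
    class = "ensemble_model"
  )
}

#' Severity index of meta-feature rows
#'
#' The logistic transform of the meta-linear predictor: the predicted
#' probability, in \[0, 1\], that the fall is severe.
#'
#' @param model an [fit_meta()] `ensemble_model`.
#' @param meta_rows a data.frame/matrix supplying all selected columns (or a
#'   `meta_features` object).
#' @return numeric vector of severity indices.
#' @export
severity_index <- function(model, meta_rows) {
  if (inherits(meta_rows, "meta_features")) meta_rows <- meta_rows$table
  missing_cols <- setdiff(model$selected_columns, colnames(meta_rows))
  if (length(missing_cols)) {
    stop("meta row is missing selected column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- as.matrix(meta_rows[, model$selected_columns, drop = FALSE])
  as.numeric(sigmoid(cbind(1, x) %*% model$meta_coefficients))
}

#' Fit the full multi-view ensemble
#'
#' Runs the whole training pipeline on one dataset: fits every (view,
#' inducer) stage-one classifier on its available rows, sets each
#' missing-substitution threshold from the training ROC curve, builds the
#' complete meta-feature table (scores + flags), wrapper-selects the best
#' subset, and fits the logistic meta-learner.
#'
#' Views whose available rows contain a single label class are dropped with a
#' warning.
#'
#' @param dataset a [multiview_dataset()].
#' @param config a [melmv_config()].
#' @param seed integer seed (drives the selection-CV partition).
#' @return an object of class `melmv_model`.
#' @export
fit_melmv <- function(dataset, config = melmv_config(), seed = 1) {
  classifiers <- fit_stage_one(dataset, config)
  meta <- build_meta_features(dataset, classifiers)
  sel <- wrapper_select(meta, folds = config$selection_folds,
                        seed = derive_seed(seed, "select"),
                        search = config$search,
                        exhaustive_limit = config$exhaustive_limit,
                        improve_tol = config$improve_tol)
  ensemble <- fit_meta(meta, sel)
  structure(
    list(classifiers = classifiers, flag_views = meta$flag_views,
         ensemble = ensemble, config = config, seed = seed),
    class = "melmv_model"
  )
}

# Fit all stage-one classifiers with thresholds; shared by MELMV and the
# meta-feature baselines.
fit_stage_one <- function(dataset, config = melmv_config()) {
  classifiers <- list()
  for (vn in names(dataset$views)) {
    vw <- dataset$views[[vn]]
    inducers <- config$inducers[[vn]] %||% c("logistic", "svm")
    for (ind in inducers) {
      clf <- tryCatch(
        fit_view_classifier(vw, dataset$labels, ind, config$learner),
        error = function(e) {
          warning("dropping ", vn, "/", ind, ": ", conditionMessage(e),
                  call. = FALSE)
          NULL
        }
      )
      if (is.null(clf)) next
      clf <- calibrate_threshold(clf, vw, dataset$labels)
      classifiers[[paste(vn, ind, sep = ".")]] <- clf
    }
  }
  if (!length(classifiers)) stop("no view classifier could be fitted", call. = FALSE)
  classifiers
}

#' @export
print.melmv_model <- function(x, ...) {
  cat(sprintf("<melmv_model: %d stage-one classifiers, %d meta-features selected (CV AUC %.3f)>\n",
              length(x$classifiers), length(x$ensemble$selected_columns),
              x$ensemble$selection_cv_auc))
  cat("  selected:", paste(x$ensemble$selected_columns, collapse = ", "), "\n")
  invisible(x)
}

#' Score new cases with a fitted ensemble
#'
#' @param object a [fit_melmv()] model.
#' @param newdata a [multiview_dataset()] in the training feature space.
#' @param ... unused.
#' @return numeric vector of severity indices, one per case.
#' @export
predict.melmv_model <- function(object, newdata, ...) {
  meta <- build_meta_features(newdata, object$classifiers,
                              flag_views = object$flag_views)
  severity_index(object$ensemble, meta)
}

#' Serialize / restore a fitted ensemble
#'
#' The JSON artifact holds every stage-one classifier's parameters, the
#' selected meta-feature subset, the meta-coefficients and the search log —
#' a full audit of the selection.
#'
#' @param model a `melmv_model`.
#' @param path output file.
#' @return `path` invisibly; `load_melmv_model()` returns the model.
#' @export
save_melmv_model <- function(model, path) {
  ens <- unclass(model$ensemble)
  ens$meta_coefficients <- as.list(ens$meta_coefficients)
  obj <- list(
    classifiers = lapply(model$classifiers, classifier_to_list),
    flag_views = model$flag_views,
    ensemble = ens,
    seed = model$seed
  )
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE, na = "null",
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_melmv_model
#' @export
load_melmv_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  classifiers <- lapply(obj$classifiers, classifier_from_list)
  ens <- obj$ensemble
  ens$meta_coefficients <- unlist(ens$meta_coefficients)
  ens$selected_columns <- unlist(ens$selected_columns)
  structure(
    list(classifiers = classifiers,
         flag_views = unlist(obj$flag_views) %||% character(0),
         ensemble = structure(ens, class = "ensemble_model"),
         config = NULL, seed = obj$seed),
    class = "melmv_model"
  )
}
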