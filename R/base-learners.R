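#' Stage-one view classifiers
#'
#' Each view is learned independently on the cases where it is available, by a
#' linear inducer (ridge-penalized logistic regression) and/or a nonlinear one
#' (support-vector machine for classification, support-vector regression for
#' the low-dimensional bone-density views). All inducers emit scores in
#' \[0, 1\] interpreted as the predicted probability of a severe fall: logistic
#' outputs are model probabilities, SVM decision values pass through a
#' Platt-style sigmoid calibration fitted on the training decision values
#' (rank-preserving), and SVR outputs are clipped to \[0, 1\].
#'
#' Fitted parameters are extracted into plain numeric form at fit time and all
#' scoring is computed from them, so classifiers serialize to JSON exactly.
#'
#' @name base-learners
NULL

#' Control parameters for the base inducers
#'
#' @param logistic_lambda ridge penalty for the logistic inducer (fixed;
#'   regularization is needed for the several-hundred-column sparse
#'   diagnosis view).
#' @param svm_cost SVM/SVR cost parameter.
#' @param svm_kernel `"linear"` (default) or `"radial"`.
#' @param svm_gamma RBF kernel width; default `1/ncol`.
#' @return a list of class `learner_control`.
#' @export
learner_control <- function(logistic_lambda = 0.01, svm_cost = 1,
                            svm_kernel = c("linear", "radial"),
                            svm_gamma = NULL) {
  structure(list(logistic_lambda = logistic_lambda, svm_cost = svm_cost,
                 svm_kernel = match.arg(svm_kernel), svm_gamma = svm_gamma),
            class = "learner_control")
}

#' Fit a stage-one classifier on one view
#'
#' Only available rows are used; unavailable rows never influence the fit.
#' Views whose available rows contain a single label class cannot be learned
#' and raise an error instructing the caller to drop the view. A view whose
#' available features are all constant yields a degenerate classifier scoring
#' 0.5 everywhere, with a warning, so pipelines on pathological inputs still
#' run.
#'
#' @param view a [view_matrix()].
#' @param labels binary labels aligned to the view's rows.
#' @param inducer `"logistic"`, `"svm"` or `"svr"`.
#' @param control a [learner_control()].
#' @return an object of class `view_classifier` with fields `params`,
#'   `calibration`, `train_auc`, and a missing-substitution `threshold`
#'   (set later by [calibrate_threshold()]).
#' @export
fit_view_classifier <- function(view, labels, inducer = c("logistic", "svm", "svr"),
                                control = learner_control()) {
  inducer <- match.arg(inducer)
  labels <- check_labels(labels, require_both = FALSE)
  stopifnot(length(labels) == length(view$available))
  avail <- view$available
  if (!any(avail)) {
    stop("view '", view$view_name, "': no available rows to fit on", call. = FALSE)
  }
  x <- view$values[avail, , drop = FALSE]
  y <- labels[avail]
  if (length(unique(y)) < 2L) {
    stop("view '", view$view_name, "': available rows contain a single label ",
         "class; drop this view from the ensemble", call. = FALSE)
  }

  col_sd <- apply(x, 2, stats::sd)
  if (all(col_sd == 0)) {
    warning("view '", view$view_name, "': all features constant; ",
            "emitting degenerate constant-score classifier", call. = FALSE)
    params <- list(type = "constant", value = 0.5)
    clf <- new_view_classifier(view, inducer, params, NULL, train_auc = 0.5)
    return(clf)
  }

  if (inducer == "logistic") {
    xg <- x
    if (ncol(xg) == 1L) xg <- cbind(xg, `.dummy` = 0)
    # small bone-density views routinely have few positives; glmnet's
    # small-class caution is expected there
    fit <- withCallingHandlers(
      glmnet::glmnet(xg, y, family = "binomial", alpha = 0,
                     lambda = control$logistic_lambda, standardize = TRUE),
      warning = function(w) {
        if (grepl("fewer than 8", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
    beta <- as.numeric(fit$beta[, 1L])
    names(beta) <- rownames(fit$beta)
    beta <- beta[colnames(view$values)]
    params <- list(type = "logistic", intercept = as.numeric(fit$a0),
                   coefficients = beta)
    calibration <- NULL
  } else if (inducer == "svm") {
    m <- e1071::svm(x, factor(y, levels = c(0, 1)), type = "C-classification",
                    kernel = control$svm_kernel, cost = control$svm_cost,
                    gamma = control$svm_gamma %||% 1 / ncol(x), scale = FALSE)
    params <- extract_svm_params(m, "svm", control)
    dec <- svm_decision(params, x)
    if (auc(dec, y) < 0.5) {
      params <- flip_svm_params(params)
      dec <- -dec
    }
    calibration <- fit_platt(dec, y)
  } else {
    m <- e1071::svm(x, as.numeric(y), type = "eps-regression",
                    kernel = control$svm_kernel, cost = control$svm_cost,
                    gamma = control$svm_gamma %||% 1 / ncol(x), scale = FALSE)
    params <- extract_svm_params(m, "svr", control)
    calibration <- NULL
  }
  clf <- new_view_classifier(view, inducer, params, calibration, train_auc = NA_real_)
  tr_scores <- score_matrix(clf, x)
  clf$train_auc <- auc(tr_scores, y)
  clf
}

new_view_classifier <- function(view, inducer, params, calibration, train_auc) {
  structure(
    list(view_name = view$view_name, inducer = inducer,
         feature_names = view$feature_names, params = params,
         calibration = calibration, threshold = NA_real_,
         train_auc = train_auc),
    class = "view_classifier"
  )
}

#' @export
print.view_classifier <- function(x, ...) {
  cat(sprintf("<view_classifier %s/%s: train AUC %.3f, threshold %s>\n",
              x$view_name, x$inducer, x$train_auc,
              if (is.na(x$threshold)) "unset" else sprintf("%.3f", x$threshold)))
  invisible(x)
}

extract_svm_params <- function(m, type, control) {
  if (control$svm_kernel == "linear") {
    w <- as.numeric(t(m$coefs) %*% m$SV)
    names(w) <- colnames(m$SV)
    list(type = type, kernel = "linear", w = w, rho = m$rho)
  } else {
    list(type = type, kernel = "radial", sv = unname(as.matrix(m$SV)),
         coefs = as.numeric(m$coefs), rho = m$rho, gamma = m$gamma)
  }
}

flip_svm_params <- function(p) {
  if (p$kernel == "linear") { p$w <- -p$w } else { p$coefs <- -p$coefs }
  p$rho <- -p$rho
  p
}

svm_decision <- function(p, x) {
  if (p$kernel == "linear") {
    as.numeric(x %*% p$w - p$rho)
  } else {
    # K(sv_i, x_j) = exp(-gamma * ||sv_i - x_j||^2)
    sv <- p$sv
    d2 <- outer(rowSums(sv^2), rowSums(x^2), "+") - 2 * tcrossprod(sv, x)
    d2[d2 < 0] <- 0
    as.numeric(crossprod(exp(-p$gamma * d2), p$coefs) - p$rho)
  }
}

# Platt-style sigmoid calibration of decision values to probabilities.
fit_platt <- function(dec, y) {
  if (stats::sd(dec) == 0) return(c(a = stats::qlogis(mean(y)), b = 0))
  cf <- suppressWarnings(
    stats::glm.fit(cbind(1, dec), y, family = stats::binomial())$coefficients)
  if (any(!is.finite(cf))) cf <- c(0, 1)
  c(a = unname(cf[1L]), b = unname(cf[2L]))
}

# Score an already feature-aligned numeric matrix.
score_matrix <- function(clf, x) {
  p <- clf$params
  switch(p$type,
    constant = rep(p$value, nrow(x)),
    logistic = as.numeric(sigmoid(p$intercept + x %*% p$coefficients)),
    svm = {
      dec <- svm_decision(p, x)
      as.numeric(sigmoid(clf$calibration[["a"]] + clf$calibration[["b"]] * dec))
    },
    svr = pmin(1, pmax(0, svm_decision(p, x))),
    stop("unknown classifier params type: ", p$type)
  )
}

#' Score a view with a fitted classifier
#'
#' @param classifier a fitted [fit_view_classifier()] object.
#' @param view a [view_matrix()] with the same feature names.
#' @return list with `scores` (numeric, `NA` at unavailable rows) and
#'   `available` (logical mask). Substitution of missing entries happens
#'   downstream in [complete_outputs()].
#' @export
predict_view <- function(classifier, view) {
  missing_f <- setdiff(classifier$feature_names, view$feature_names)
  extra_f <- setdiff(view$feature_names, classifier$feature_names)
  if (length(missing_f) || length(extra_f)) {
    stop("feature mismatch for view '", view$view_name, "': missing [",
         paste(utils::head(missing_f, 5L), collapse = ", "), "], extra [",
         paste(utils::head(extra_f, 5L), collapse = ", "), "]", call. = FALSE)
  }
  scores <- rep(NA_real_, nrow(view$values))
  if (any(view$available)) {
    x <- view$values[view$available, classifier$feature_names, drop = FALSE]
    scores[view$available] <- score_matrix(classifier, x)
  }
  list(scores = scores, available = view$available)
}

#' Set the missing-substitution threshold of a classifier
#'
#' The threshold is the Youden-optimal ROC cutoff of the classifier's own
#' training scores (computed on the same available rows it was fit on); it is
#' the value substituted for cases where the view is missing.
#'
#' @param classifier a fitted `view_classifier`.
#' @param view the training [view_matrix()].
#' @param labels training labels.
#' @return the classifier with `threshold` set.
#' @export
calibrate_threshold <- function(classifier, view, labels) {
  pr <- predict_view(classifier, view)
  sc <- pr$scores[pr$available]
  y <- labels[pr$available]
  classifier$threshold <- youden_threshold(sc, y)
  classifier
}

#' Serialize / restore a view classifier
#'
#' Coefficients, support-vector expansions and calibration parameters are
#' written as full-precision JSON; the round trip is exact.
#'
#' @param classifier a `view_classifier`.
#' @param path output file.
#' @return `path` invisibly (`save_classifier`); the classifier
#'   (`load_classifier`).
#' @export
save_classifier <- function(classifier, path) {
  jsonlite::write_json(classifier_to_list(classifier), path, digits = I(17),
                       auto_unbox = TRUE, na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  classifier_from_list(jsonlite::read_json(path, simplifyVector = TRUE))
}

# JSON-friendly form: named numeric vectors become named lists (jsonlite
# drops the names of atomic vectors otherwise).
classifier_to_list <- function(clf) {
  out <- unclass(clf)
  if (!is.null(out$params$coefficients)) {
    out$params$coefficients <- as.list(out$params$coefficients)
  }
  if (!is.null(out$params$w)) out$params$w <- as.list(out$params$w)
  if (!is.null(out$calibration)) out$calibration <- as.list(out$calibration)
  out
}

classifier_from_list <- function(obj) {
  if (!is.null(obj$params$coefficients)) {
    obj$params$coefficients <- unlist(obj$params$coefficients)
  }
  if (!is.null(obj$params$w)) obj$params$w <- unlist(obj$params$w)
  if (!is.null(obj$params$sv)) obj$params$sv <- as.matrix(obj$params$sv)
  if (!is.null(obj$calibration)) obj$calibration <- unlist(obj$calibration)
  obj$feature_names <- unlist(obj$feature_names)
  obj$threshold <- obj$threshold %||% NA_real_
  obj$train_auc <- obj$train_auc %||% NA_real_
  structure(obj, class = "view_classifier")
}
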