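#' Evaluation machinery
#'
#' Rank-based AUC with tie correction, DeLong and bootstrap confidence
#' intervals, repeated stratified cross-validation of whole pipelines, and
#' operating-point reporting (specificity at a target sensitivity).
#'
#' @name evaluation
NULL

#' Area under the ROC curve
#'
#' Rank-based AUC with tie correction; equals the mean over all
#' positive-negative pairs of `1[s+ > s-] + 0.5 * 1[s+ == s-]`.
#'
#' @param scores numeric scores (any scale; AUC is rank-invariant).
#' @param labels binary labels; both classes must be present.
#' @return AUC in \[0, 1\].
#' @examples
#' auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)) # 1
#' @export
auc <- function(scores, labels) {
  labels <- check_labels(labels)
  if (length(scores) != length(labels)) stop("scores/labels length mismatch", call. = FALSE)
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  r <- rank(scores)
  n1 <- sum(labels == 1L)
  n0 <- length(labels) - n1
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Placement values: for each positive, the fraction of negatives it beats
# (ties half-credited), and symmetrically for negatives. DeLong's structural
# components.
placement_values <- function(scores, labels) {
  x <- scores[labels == 1L]
  y <- scores[labels == 0L]
  sy <- sort(y); sx <- sort(x)
  m <- length(x); n <- length(y)
  lt <- findInterval(x, sy, left.open = TRUE)   # negatives < each positive
  le <- findInterval(x, sy)                     # negatives <= each positive
  v10 <- (lt + 0.5 * (le - lt)) / n
  lt0 <- findInterval(y, sx, left.open = TRUE)
  le0 <- findInterval(y, sx)
  v01 <- 1 - (lt0 + 0.5 * (le0 - lt0)) / m      # positives > each negative
  list(v10 = v10, v01 = v01)
}

#' DeLong confidence interval for the AUC
#'
#' Variance from the DeLong structural-components estimator:
#' `var(V10)/m + var(V01)/n`, where `V10`/`V01` are the per-positive and
#' per-negative placement values. The interval is a normal approximation
#' clipped to \[0, 1\].
#'
#' @param scores numeric scores.
#' @param labels binary labels (>= 2 cases per class).
#' @param alpha two-sided error rate (default 0.05).
#' @return list with `auc`, `variance`, `ci_low`, `ci_high`.
#' @export
delong_ci <- function(scores, labels, alpha = 0.05) {
  labels <- check_labels(labels)
  if (sum(labels == 1L) < 2L || sum(labels == 0L) < 2L) {
    stop("DeLong interval needs at least 2 cases per class", call. = FALSE)
  }
  pv <- placement_values(scores, labels)
  a <- mean(pv$v10)
  v <- stats::var(pv$v10) / length(pv$v10) + stats::var(pv$v01) / length(pv$v01)
  if (a %in% c(0, 1) || v == 0) {
    warning("degenerate AUC (perfect or null separation): zero-variance interval",
            call. = FALSE)
    return(list(auc = a, variance = 0, ci_low = a, ci_high = a))
  }
  z <- stats::qnorm(1 - alpha / 2)
  list(auc = a, variance = v,
       ci_low = max(0, a - z * sqrt(v)),
       ci_high = min(1, a + z * sqrt(v)))
}

#' Percentile bootstrap interval for a sample statistic
#'
#' Resamples a vector (e.g. the per-repeat AUCs of repeated cross-validation)
#' with replacement and returns the percentile interval of the statistic.
#'
#' @param x numeric sample.
#' @param statistic function of a numeric vector (default [mean()]).
#' @param B number of resamples.
#' @param alpha two-sided error rate.
#' @param seed integer seed.
#' @return list with `estimate`, `ci_low`, `ci_high`.
#' @export
bootstrap_ci <- function(x, statistic = mean, B = 2000, alpha = 0.05, seed = 1) {
  stopifnot(B >= 2, length(x) >= 1)
  set.seed(seed)
  stats_b <- vapply(seq_len(B), function(b) {
    statistic(x[sample.int(length(x), replace = TRUE)])
  }, 0)
  q <- stats::quantile(stats_b, c(alpha / 2, 1 - alpha / 2), names = FALSE, type = 7)
  list(estimate = statistic(x), ci_low = q[1L], ci_high = q[2L])
}

#' Case-level stratified bootstrap interval for the AUC
#'
#' Positives and negatives are resampled separately, so every resample
#' contains both classes.
#'
#' @param scores numeric scores.
#' @param labels binary labels.
#' @inheritParams bootstrap_ci
#' @return list with `estimate` (the observed AUC), `ci_low`, `ci_high`.
#' @export
bootstrap_auc_ci <- function(scores, labels, B = 2000, alpha = 0.05, seed = 1) {
  labels <- check_labels(labels)
  stopifnot(B >= 2)
  set.seed(seed)
  ip <- which(labels == 1L); im <- which(labels == 0L)
  aucs <- vapply(seq_len(B), function(b) {
    idx <- c(sample(ip, replace = TRUE), sample(im, replace = TRUE))
    auc(scores[idx], labels[idx])
  }, 0)
  q <- stats::quantile(aucs, c(alpha / 2, 1 - alpha / 2), names = FALSE, type = 7)
  list(estimate = auc(scores, labels), ci_low = q[1L], ci_high = q[2L])
}

#' Specificity at a target sensitivity
#'
#' Among cutoffs achieving sensitivity >= `target_sens` (rule: score >= cutoff
#' predicts positive), returns the one with maximal specificity. Since
#' sensitivity decreases and specificity increases in the cutoff, this is the
#' largest candidate cutoff still meeting the sensitivity floor.
#'
#' @param scores numeric scores in \[0, 1\].
#' @param labels binary labels.
#' @param target_sens required sensitivity, in (0, 1].
#' @return list with `sensitivity`, `specificity`, `cutoff`.
#' @export
specificity_at_sensitivity <- function(scores, labels, target_sens = 0.8) {
  labels <- check_labels(labels)
  stopifnot(target_sens > 0, target_sens <= 1)
  u <- sort(unique(scores))
  cand <- if (length(u) == 1L) u else
    unique(pmin(1, pmax(0, c(0, (u[-length(u)] + u[-1L]) / 2, 1))))
  sp <- sort(scores[labels == 1L]); sn <- sort(scores[labels == 0L])
  n1 <- length(sp); n0 <- length(sn)
  sens <- (n1 - findInterval(cand, sp, left.open = TRUE)) / n1
  spec <- findInterval(cand, sn, left.open = TRUE) / n0
  ok <- which(sens >= target_sens)
  i <- ok[length(ok)]  # largest qualifying cutoff has maximal specificity
  list(sensitivity = sens[i], specificity = spec[i], cutoff = cand[i])
}

#' ROC curve points
#'
#' @param scores numeric scores.
#' @param labels binary labels.
#' @return data.frame with `cutoff`, `fpr`, `tpr` (one row per candidate
#'   cutoff), suitable for plotting or CSV export.
#' @export
roc_points <- function(scores, labels) {
  labels <- check_labels(labels)
  u <- sort(unique(scores))
  cand <- unique(pmin(1e300, pmax(-1e300, c(min(u) - 1, (u[-length(u)] + u[-1L]) / 2,
                                            max(u) + 1))))
  sp <- sort(scores[labels == 1L]); sn <- sort(scores[labels == 0L])
  tpr <- (length(sp) - findInterval(cand, sp, left.open = TRUE)) / length(sp)
  fpr <- (length(sn) - findInterval(cand, sn, left.open = TRUE)) / length(sn)
  data.frame(cutoff = cand, fpr = fpr, tpr = tpr)
}

#' Repeated stratified k-fold cross-validation of a pipeline
#'
#' For each repeat a fresh stratified partition is drawn; the entire pipeline
#' is refit inside every training fold via `fit_fun` and its held-out fold is
#' scored via `predict_fun`; the pooled out-of-fold scores of a repeat yield
#' one AUC.
#'
#' @param dataset a [multiview_dataset()].
#' @param fit_fun `function(train_dataset, seed)` returning a fitted model.
#' @param predict_fun `function(model, test_dataset)` returning scores.
#' @param repeats number of repeats (default 10).
#' @param folds folds per repeat (default 10).
#' @param seed integer seed; fully determines all partitions.
#' @return numeric vector of `repeats` AUC values, with the per-repeat pooled
#'   out-of-fold scores attached as attribute `"oof_scores"` (a matrix,
#'   cases x repeats).
#' @export
repeated_kfold_cv <- function(dataset, fit_fun, predict_fun,
                              repeats = 10, folds = 10, seed = 1) {
  labels <- check_labels(dataset$labels)
  aucs <- numeric(repeats)
  oof <- matrix(NA_real_, length(labels), repeats)
  for (r in seq_len(repeats)) {
    fold <- stratified_folds(labels, folds, derive_seed(seed, paste0("cv-rep", r)))
    for (k in seq_len(folds)) {
      tr <- subset_dataset(dataset, fold != k)
      te <- subset_dataset(dataset, fold == k)
      model <- fit_fun(tr, derive_seed(seed, paste0("cv-fit", r, "-", k)))
      oof[fold == k, r] <- predict_fun(model, te)
    }
    aucs[r] <- auc(oof[, r], labels)
  }
  attr(aucs, "oof_scores") <- oof
  aucs
}

#' Evaluation report for a score vector or a CV run
#'
#' @param scores numeric scores (held-out evaluation) — or `NULL` when
#'   `per_repeat_aucs` is given (CV evaluation, bootstrap CI over repeats).
#' @param labels binary labels (required with `scores`).
#' @param ci_method `"delong"` or `"bootstrap"` (held-out mode).
#' @param per_repeat_aucs numeric vector of repeat-level AUCs (CV mode).
#' @param sens_targets sensitivities at which to report operating points.
#' @param B,alpha,seed bootstrap parameters.
#' @return an object of class `eval_report`.
#' @export
eval_report <- function(scores = NULL, labels = NULL,
                        ci_method = c("delong", "bootstrap"),
                        per_repeat_aucs = NULL, sens_targets = 0.8,
                        B = 2000, alpha = 0.05, seed = 1) {
  ci_method <- match.arg(ci_method)
  if (!is.null(per_repeat_aucs)) {
    bs <- bootstrap_ci(per_repeat_aucs, mean, B = B, alpha = alpha, seed = seed)
    rep <- list(auc = mean(per_repeat_aucs), ci_low = bs$ci_low,
                ci_high = bs$ci_high, ci_method = "bootstrap",
                per_repeat_aucs = as.numeric(per_repeat_aucs),
                operating_points = NULL)
  } else {
    stopifnot(!is.null(scores), !is.null(labels))
    if (ci_method == "delong") {
      d <- delong_ci(scores, labels, alpha)
      ci <- c(d$ci_low, d$ci_high); a <- d$auc
    } else {
      b <- bootstrap_auc_ci(scores, labels, B = B, alpha = alpha, seed = seed)
      ci <- c(b$ci_low, b$ci_high); a <- b$estimate
    }
    ops <- lapply(sens_targets, function(ts) {
      op <- specificity_at_sensitivity(scores, labels, ts)
      data.frame(target = ts, sensitivity = op$sensitivity,
                 specificity = op$specificity, cutoff = op$cutoff)
    })
    rep <- list(auc = a, ci_low = min(ci[1L], a), ci_high = max(ci[2L], a),
                ci_method = ci_method, per_repeat_aucs = NULL,
                operating_points = do.call(rbind, ops))
  }
  structure(rep, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("AUC %.3f (95%% CI %.3f-%.3f, %s)\n",
              x$auc, x$ci_low, x$ci_high, x$ci_method))
  if (!is.null(x$per_repeat_aucs)) {
    cat(sprintf("  %d CV repeats, range %.3f-%.3f\n", length(x$per_repeat_aucs),
                min(x$per_repeat_aucs), max(x$per_repeat_aucs)))
  }
  if (!is.null(x$operating_points)) {
    apply(x$operating_points, 1L, function(r) {
      cat(sprintf("  at sensitivity >= %.0f%%: sensitivity %.3f, specificity %.3f (cutoff %.3f)\n",
                  100 * as.numeric(r[["target"]]), as.numeric(r[["sensitivity"]]),
                  as.numeric(r[["specificity"]]), as.numeric(r[["cutoff"]])))
    })
  }
  invisible(x)
}

#' Superiority comparison between two models
#'
#' A model is declared statistically significantly better than another when
#' its 95% confidence interval lies entirely above the other model's mean AUC.
#'
#' @param report an [eval_report()] for the candidate model.
#' @param other_auc the comparator's mean AUC (or its `eval_report`).
#' @return logical.
#' @export
is_superior <- function(report, other_auc) {
  if (inherits(other_auc, "eval_report")) other_auc <- other_auc$auc
  report$ci_low > other_auc
}
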