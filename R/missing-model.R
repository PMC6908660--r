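#' Model-based handling of missing views
#'
#' Instead of imputing raw features, a missing view's classifier output is
#' replaced by that classifier's optimal ROC cutoff (the score maximizing
#' sensitivity + specificity on the training rows where the view is
#' available), and a binary missing flag records whether each output is a real
#' prediction or a substituted threshold. The completed score columns and the
#' flags together form the meta-feature table consumed by the ensemble.
#'
#' A substituted case sits exactly at the decision boundary of its classifier:
#' under the rule "score >= threshold predicts severe", substituted cases fall
#' on the positive side, which is why the flag is needed to let the
#' meta-learner discount (or exploit) substituted outputs.
#'
#' @name missing-model
NULL

#' Youden-optimal ROC cutoff
#'
#' Returns the cutoff `t` maximizing sensitivity(t) + specificity(t) under the
#' classification rule `score >= t` => predicted positive. Candidate cutoffs
#' are the midpoints between adjacent distinct sorted scores plus the two
#' sentinels below/above all scores, clipped into \[0, 1\]; ties are broken
#' toward the smallest maximizing candidate. When all scores are identical
#' there is no interior candidate and that score itself is returned (every
#' cutoff at or below it is equivalent, with sensitivity + specificity = 1).
#'
#' @param scores numeric scores in \[0, 1\].
#' @param labels binary labels; both classes must be present.
#' @return the selected cutoff, a number in \[0, 1\].
#' @examples
#' youden_threshold(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)) # 0.5
#' @export
youden_threshold <- function(scores, labels) {
  labels <- check_labels(labels)
  if (length(scores) != length(labels)) stop("scores/labels length mismatch", call. = FALSE)
  if (any(!is.finite(scores)) || any(scores < 0 | scores > 1)) {
    stop("scores must be finite and lie in [0, 1]", call. = FALSE)
  }
  u <- sort(unique(scores))
  if (length(u) == 1L) return(u)
  cand <- unique(pmin(1, pmax(0, c(0, (u[-length(u)] + u[-1L]) / 2, 1))))
  J <- youden_J(scores, labels, cand)
  cand[which(J == max(J))[1L]]
}

# Sensitivity + specificity at each candidate cutoff, via sorted-score counts.
youden_J <- function(scores, labels, cand) {
  sp <- sort(scores[labels == 1L])
  sn <- sort(scores[labels == 0L])
  n1 <- length(sp); n0 <- length(sn)
  tp <- n1 - findInterval(cand, sp, left.open = TRUE)
  fp <- n0 - findInterval(cand, sn, left.open = TRUE)
  tp / n1 + (n0 - fp) / n0
}

#' Complete a score vector by threshold substitution
#'
#' @param scored either the list returned by [predict_view()] or a numeric
#'   vector with `NA` marking missing entries.
#' @param threshold the substitution value, in \[0, 1\].
#' @return a gap-free numeric score vector; available entries are unchanged.
#' @export
complete_outputs <- function(scored, threshold) {
  if (!is.finite(threshold) || threshold < 0 || threshold > 1) {
    stop("threshold must lie in [0, 1]", call. = FALSE)
  }
  if (is.list(scored)) {
    scores <- scored$scores
    miss <- !scored$available
  } else {
    scores <- scored
    miss <- is.na(scores)
  }
  scores[miss] <- threshold
  scores
}

#' Missing flag column for a view
#'
#' @param available logical availability mask.
#' @return integer vector (1 = missing/substituted, 0 = observed), or `NULL`
#'   when the view has no missing cases (no flag column is emitted then).
#' @export
missing_flag <- function(available) {
  if (all(available)) return(NULL)
  as.integer(!available)
}

#' Build the meta-feature table
#'
#' One completed score column per fitted (view, inducer) classifier, plus one
#' missing-flag column per view that has any missing cases in this cohort
#' (or per `flag_views`, when transforming new data with the flag roster fixed
#' at training time).
#'
#' @param dataset a [multiview_dataset()].
#' @param classifiers named list of fitted classifiers with thresholds set.
#' @param flag_views optional character vector freezing which views get flag
#'   columns; default: determined from this dataset's missingness.
#' @return an object of class `meta_features`: a case-aligned gap-free table,
#'   labels, and a column-provenance map (view, inducer, kind).
#' @export
build_meta_features <- function(dataset, classifiers, flag_views = NULL) {
  stopifnot(length(classifiers) > 0L)
  cols <- list()
  prov <- list()
  for (clf in classifiers) {
    if (is.na(clf$threshold)) {
      stop("classifier ", clf$view_name, "/", clf$inducer,
           " has no substitution threshold; call calibrate_threshold() first",
           call. = FALSE)
    }
    vw <- dataset$views[[clf$view_name]]
    if (is.null(vw)) stop("dataset has no view '", clf$view_name, "'", call. = FALSE)
    nm <- paste(clf$view_name, clf$inducer, sep = ".")
    cols[[nm]] <- complete_outputs(predict_view(clf, vw), clf$threshold)
    prov[[nm]] <- data.frame(name = nm, view = clf$view_name,
                             inducer = clf$inducer, kind = "score",
                             stringsAsFactors = FALSE)
  }
  used_views <- unique(vapply(classifiers, `[[`, "", "view_name"))
  if (is.null(flag_views)) {
    flag_views <- used_views[vapply(used_views, function(vn) {
      any(!dataset$views[[vn]]$available)
    }, TRUE)]
  }
  for (vn in flag_views) {
    nm <- paste0("flag.", vn)
    cols[[nm]] <- as.integer(!dataset$views[[vn]]$available)
    prov[[nm]] <- data.frame(name = nm, view = vn, inducer = NA_character_,
                             kind = "flag", stringsAsFactors = FALSE)
  }
  tab <- as.data.frame(cols, check.names = FALSE, optional = TRUE)
  if (anyNA(tab)) {
    stop("internal error: meta-feature table contains gaps after substitution")
  }
  structure(
    list(table = tab, labels = dataset$labels, case_ids = dataset$case_ids,
         columns = do.call(rbind, prov), flag_views = flag_views),
    class = "meta_features"
  )
}

#' @export
print.meta_features <- function(x, ...) {
  cat(sprintf("<meta_features: %d cases, %d score + %d flag columns>\n",
              nrow(x$table), sum(x$columns$kind == "score"),
              sum(x$columns$kind == "flag")))
  invisible(x)
}

#' Persist a meta-feature table to CSV
#'
#' The header carries commented provenance lines (`# name,view,inducer,kind`)
#' documenting each column's origin.
#'
#' @param meta a `meta_features` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
save_meta_features <- function(meta, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# column provenance: name,view,inducer,kind", con)
  apply(meta$columns, 1L, function(r) {
    writeLines(paste0("# ", paste(r, collapse = ",")), con)
  })
  df <- cbind(data.frame(case_id = meta$case_ids, label = meta$labels,
                         stringsAsFactors = FALSE),
              meta$table)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}
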