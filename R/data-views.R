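#' Multi-view cohort data model
#'
#' A cohort of fall incidents is represented as a set of aligned *views*: one
#' numeric feature matrix per data source (demographics, diagnosis-category
#' indicators, procedure indicators, and the two bone-density measurement
#' types), each with a per-case availability mask. Demographics and diagnoses
#' are recorded for every case; procedures and bone density are frequently
#' missing, which is the regime the ensemble's missing-data device targets.
#'
#' @name multiview-data
NULL

CANONICAL_VIEWS <- c("demographics", "diagnoses", "procedures",
                     "bd_forearm", "bd_dual_femur")

#' Construct a view matrix
#'
#' @param view_name name of the data source.
#' @param values numeric matrix (cases x features) with column names; rows for
#'   unavailable cases carry `NA` and are never read by learners.
#' @param available logical vector, one entry per case.
#' @return an object of class `view_matrix`.
#' @export
view_matrix <- function(view_name, values, available) {
  values <- as.matrix(values)
  if (is.null(colnames(values))) {
    stop("view '", view_name, "': values must have column names", call. = FALSE)
  }
  available <- as.logical(available)
  if (nrow(values) != length(available)) {
    stop("view '", view_name, "': row count (", nrow(values),
         ") does not match availability mask length (", length(available), ")",
         call. = FALSE)
  }
  if (any(available) && any(!is.finite(values[available, , drop = FALSE]))) {
    stop("view '", view_name, "': non-finite values in available rows", call. = FALSE)
  }
  values[!available, ] <- NA_real_
  structure(
    list(view_name = view_name, values = values,
         feature_names = colnames(values), available = available),
    class = "view_matrix"
  )
}

#' @export
print.view_matrix <- function(x, ...) {
  cat(sprintf("<view_matrix '%s': %d cases x %d features, %.1f%% available>\n",
              x$view_name, nrow(x$values), ncol(x$values),
              100 * mean(x$available)))
  invisible(x)
}

#' Construct a multi-view dataset
#'
#' @param case_ids character vector of unique case identifiers.
#' @param labels binary vector, 1 = severe fall.
#' @param views list of [view_matrix()] objects, all aligned to `case_ids`.
#' @param harm_scores optional integer vector of AHRQ harm scores (1-9); when
#'   present it must be consistent with `labels` under [harm_to_label()].
#' @return an object of class `multiview_dataset`.
#' @export
multiview_dataset <- function(case_ids, labels, views, harm_scores = NULL) {
  case_ids <- as.character(case_ids)
  if (anyDuplicated(case_ids)) {
    stop("duplicate case ids: ",
         paste(unique(case_ids[duplicated(case_ids)]), collapse = ", "),
         call. = FALSE)
  }
  labels <- check_labels(labels, require_both = FALSE)
  if (length(labels) != length(case_ids)) {
    stop("labels length does not match case_ids", call. = FALSE)
  }
  if (is.null(names(views))) names(views) <- vapply(views, `[[`, "", "view_name")
  for (v in views) {
    stopifnot(inherits(v, "view_matrix"))
    if (nrow(v$values) != length(case_ids)) {
      stop("view '", v$view_name, "' is not aligned to case_ids", call. = FALSE)
    }
  }
  if (!is.null(harm_scores)) {
    bad <- which(harm_scores < 1 | harm_scores > 9 | harm_scores != round(harm_scores))
    if (length(bad)) {
      stop("harm score out of range 1-9 for case id(s): ",
           paste(case_ids[bad], collapse = ", "), call. = FALSE)
    }
    if (!all(harm_to_label(harm_scores) == labels)) {
      stop("labels are inconsistent with harm scores under the >=6 severity rule",
           call. = FALSE)
    }
    harm_scores <- as.integer(harm_scores)
  }
  structure(
    list(case_ids = case_ids, labels = labels, views = views,
         harm_scores = harm_scores),
    class = "multiview_dataset"
  )
}

#' @export
print.multiview_dataset <- function(x, ...) {
  cat(sprintf("<multiview_dataset: %d cases, prevalence %.1f%%>\n",
              length(x$case_ids), 100 * mean(x$labels)))
  for (v in x$views) {
    cat(sprintf("  %-14s %4d features, %5.1f%% available\n",
                v$view_name, ncol(v$values), 100 * mean(v$available)))
  }
  invisible(x)
}

#' Binarize an AHRQ harm score
#'
#' Fall incidents are graded 1-9 on the AHRQ Common Format harm scale; a score
#' of 6 or above indicates significant harm and defines a severe fall.
#'
#' @param harm_score integer vector of harm scores in 1-9.
#' @param case_id optional identifiers used in validation messages.
#' @return integer vector, 1 for severe (harm >= 6), 0 otherwise.
#' @examples
#' harm_to_label(c(1, 5, 6, 9))
#' @export
harm_to_label <- function(harm_score, case_id = NULL) {
  bad <- which(!is.finite(harm_score) | harm_score < 1 | harm_score > 9 |
                 harm_score != round(harm_score))
  if (length(bad)) {
    who <- if (is.null(case_id)) paste("index", bad) else case_id[bad]
    stop("harm score out of range 1-9 for case id(s): ",
         paste(who, collapse = ", "), call. = FALSE)
  }
  as.integer(harm_score >= 6)
}

#' Subset a multi-view dataset by case index
#'
#' @param dataset a [multiview_dataset()].
#' @param idx integer or logical index over cases.
#' @return the subsetted `multiview_dataset`.
#' @export
subset_dataset <- function(dataset, idx) {
  views <- lapply(dataset$views, function(v) {
    view_matrix(v$view_name, v$values[idx, , drop = FALSE], v$available[idx])
  })
  multiview_dataset(dataset$case_ids[idx], dataset$labels[idx], views,
                    harm_scores = dataset$harm_scores[idx])
}

#' Stratified train/test split
#'
#' @param dataset a [multiview_dataset()].
#' @param test_frac fraction of cases held out, stratified by label.
#' @param seed integer seed.
#' @return list with elements `train` and `test`.
#' @export
train_test_split <- function(dataset, test_frac = 0.25, seed = 1) {
  stopifnot(test_frac > 0, test_frac < 1)
  set.seed(seed)
  test <- logical(length(dataset$labels))
  for (cl in c(0L, 1L)) {
    idx <- which(dataset$labels == cl)
    test[sample(idx, round(test_frac * length(idx)))] <- TRUE
  }
  list(train = subset_dataset(dataset, !test),
       test  = subset_dataset(dataset, test))
}
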