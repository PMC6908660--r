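#' Cohort file I/O
#'
#' A cohort on disk is a directory with one CSV per view, a labels CSV
#' (case_id, harm_score, label), and a YAML manifest naming them. Numeric
#' values are written with 17 significant digits so a save/load round trip
#' reproduces the dataset exactly.
#'
#' @name cohort-io
NULL

fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) NA_character_ else sprintf("%.17g", v)
  }, "")
  out
}

write_table_exact <- function(df, path) {
  num <- vapply(df, is.double, TRUE)
  for (j in which(num)) df[[j]] <- fmt_num(df[[j]])
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, na = "")
}

#' Save a multi-view dataset to a directory
#'
#' @param dataset a [multiview_dataset()].
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
save_cohort <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(views = list(), labels = "labels.csv")
  harm <- dataset$harm_scores %||% ifelse(dataset$labels == 1L, 6L, 1L)
  labs <- data.frame(case_id = dataset$case_ids, harm_score = harm,
                     label = dataset$labels, stringsAsFactors = FALSE)
  write_table_exact(labs, file.path(dir, "labels.csv"))
  for (v in dataset$views) {
    fn <- paste0("view_", v$view_name, ".csv")
    df <- data.frame(case_id = dataset$case_ids,
                     available = as.integer(v$available),
                     stringsAsFactors = FALSE, check.names = FALSE)
    vals <- as.data.frame(v$values, check.names = FALSE)
    df <- cbind(df, vals)
    write_table_exact(df, file.path(dir, fn))
    manifest$views[[v$view_name]] <- fn
  }
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, path)
  invisible(path)
}

#' Load a multi-view dataset from a manifest
#'
#' @param manifest_path path to the `manifest.yaml` written by [save_cohort()]
#'   (or a directory containing one).
#' @return a [multiview_dataset()].
#' @export
load_cohort <- function(manifest_path) {
  if (dir.exists(manifest_path)) {
    manifest_path <- file.path(manifest_path, "manifest.yaml")
  }
  if (!file.exists(manifest_path)) {
    stop("manifest not found: ", manifest_path, call. = FALSE)
  }
  manifest <- yaml::read_yaml(manifest_path)
  base <- dirname(manifest_path)
  lab_path <- file.path(base, manifest$labels)
  if (!file.exists(lab_path)) stop("labels file not found: ", lab_path, call. = FALSE)
  labs <- utils::read.csv(lab_path, stringsAsFactors = FALSE, check.names = FALSE)
  case_ids <- as.character(labs$case_id)
  if (anyDuplicated(case_ids)) {
    stop("duplicate case ids in labels file: ",
         paste(unique(case_ids[duplicated(case_ids)]), collapse = ", "),
         call. = FALSE)
  }
  harm <- NULL
  if ("harm_score" %in% names(labs)) {
    harm <- labs$harm_score
    labels <- harm_to_label(harm, case_ids)
  } else if ("label" %in% names(labs)) {
    labels <- labs$label
  } else {
    stop("labels file must contain a harm_score or label column", call. = FALSE)
  }

  missing_views <- setdiff(CANONICAL_VIEWS, names(manifest$views))
  if (length(missing_views)) {
    stop("manifest is missing canonical view(s): ",
         paste(missing_views, collapse = ", "), call. = FALSE)
  }
  views <- list()
  for (vn in names(manifest$views)) {
    vp <- file.path(base, manifest$views[[vn]])
    if (!file.exists(vp)) stop("view file for '", vn, "' not found: ", vp, call. = FALSE)
    df <- utils::read.csv(vp, stringsAsFactors = FALSE, check.names = FALSE)
    ids <- as.character(df$case_id)
    if (!identical(ids, case_ids)) {
      off <- union(setdiff(ids, case_ids), setdiff(case_ids, ids))
      if (length(off) == 0L) off <- "(same ids, different order)"
      stop("case ids in view '", vn, "' are misaligned with labels: ",
           paste(utils::head(off, 10L), collapse = ", "), call. = FALSE)
    }
    avail <- as.logical(df$available)
    vals <- as.matrix(df[, setdiff(names(df), c("case_id", "available")),
                         drop = FALSE])
    storage.mode(vals) <- "double"
    views[[vn]] <- view_matrix(vn, vals, avail)
  }
  multiview_dataset(case_ids, labels, views, harm_scores = harm)
}
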