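#' Encoders from raw case records to view matrices
#'
#' Raw case records (one row per fall incident, with list-columns for codes
#' and bone-density measurements) are turned into numeric view matrices by
#' fit/transform-separable encoders: fitting learns cohort-level parameters
#' (age mean/SD, the observed diagnosis-category vocabulary, the CPT-code
#' vocabulary) and transforming applies them to any record set, so a model
#' trained on one cohort can score new cases in the same feature space.
#'
#' @name encoders
NULL

RACE_LEVELS <- c("asian", "black", "caucasian", "hispanic", "amer_indian",
                 "other_unknown")
RACE_REFERENCE <- "caucasian"

#' Validate a raw case-record table
#'
#' Records are a `data.frame` with columns `case_id`, `age`, `sex`, `race`,
#' `harm_score` and list-columns `diagnosis_codes`, `procedure_codes`,
#' `bd_forearm`, `bd_dual_femur` (each bone-density entry is `NULL` or a
#' named numeric `c(bmd=, t_score=)`).
#'
#' @param records case-record data.frame.
#' @return the records, invisibly, after validation.
#' @export
validate_records <- function(records) {
  needed <- c("case_id", "age", "sex", "race", "harm_score",
              "diagnosis_codes", "procedure_codes", "bd_forearm", "bd_dual_femur")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    stop("records are missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(records) == 0L) stop("empty record list", call. = FALSE)
  if (any(!is.finite(records$age) | records$age <= 0)) {
    stop("age must be a positive number for every case", call. = FALSE)
  }
  if (!all(records$sex %in% c("female", "male"))) {
    stop("sex must be 'female' or 'male'", call. = FALSE)
  }
  harm_to_label(records$harm_score, records$case_id)
  for (bd in c("bd_forearm", "bd_dual_femur")) {
    ok <- vapply(records[[bd]], function(m) {
      is.null(m) || (all(c("bmd", "t_score") %in% names(m)) &&
                       all(is.finite(m[c("bmd", "t_score")])) && m[["bmd"]] > 0)
    }, TRUE)
    if (!all(ok)) {
      stop(bd, ": available measurements must have finite t_score and bmd > 0 ",
           "(case ids: ", paste(records$case_id[!ok], collapse = ", "), ")",
           call. = FALSE)
    }
  }
  invisible(records)
}

#' Fit the demographics encoder
#'
#' Age is standardized with the fitting cohort's mean and SD; sex and race are
#' one-hot encoded with one reference level dropped (male, caucasian).
#'
#' @param records case records (see [validate_records()]).
#' @return an encoder object of class `melmv_encoder`.
#' @export
fit_demographics_encoder <- function(records) {
  validate_records(records)
  structure(
    list(view = "demographics",
         age_mean = mean(records$age),
         age_sd = stats::sd(records$age)),
    class = c("demographics_encoder", "melmv_encoder")
  )
}

#' Fit the diagnosis-category encoder
#'
#' ICD-9 codes are collapsed to their hierarchy category (by default the
#' 3-character stem before the decimal point), duplicates within a case are
#' dropped, and the feature space is the union of categories observed in the
#' fitting cohort. Codes that cannot be collapsed (shorter than the stem
#' length) are kept verbatim with a warning rather than dropped silently.
#'
#' @param records case records.
#' @param category_level number of leading characters defining a category.
#' @return an encoder object.
#' @export
fit_diagnosis_encoder <- function(records, category_level = 3L) {
  validate_records(records)
  cats <- sort(unique(unlist(lapply(records$diagnosis_codes,
                                    collapse_icd9, category_level))))
  structure(
    list(view = "diagnoses", categories = cats, category_level = category_level),
    class = c("diagnosis_encoder", "melmv_encoder")
  )
}

# Collapse ICD-9 codes to their hierarchy stem (prefix before the dot,
# truncated/validated to `level` characters for plain numeric codes).
collapse_icd9 <- function(codes, level = 3L) {
  if (length(codes) == 0L) return(character(0))
  if (any(!nzchar(codes))) stop("empty diagnosis code string", call. = FALSE)
  stem <- sub("\\..*$", "", codes)
  short <- nchar(stem) < level & !grepl("^[EV]", stem)
  if (any(short)) {
    warning("diagnosis code(s) shorter than the category stem kept verbatim: ",
            paste(unique(stem[short]), collapse = ", "), call. = FALSE)
  }
  long <- nchar(stem) > level & !grepl("^[EV]", stem)
  stem[long] <- substr(stem[long], 1L, level)
  unique(stem)
}

#' Fit the procedure encoder
#'
#' CPT codes become binary indicators over the fitting cohort's vocabulary.
#' A case with no procedure code is treated as having the view *missing*
#' (the cohort accounting counts procedure availability this way); set
#' `absent_as_missing = FALSE` to encode it as an all-zero available row.
#'
#' @param records case records.
#' @param absent_as_missing logical availability rule (default `TRUE`).
#' @return an encoder object.
#' @export
fit_procedure_encoder <- function(records, absent_as_missing = TRUE) {
  validate_records(records)
  codes <- sort(unique(unlist(records$procedure_codes)))
  structure(
    list(view = "procedures", codes = codes, absent_as_missing = absent_as_missing),
    class = c("procedure_encoder", "melmv_encoder")
  )
}

#' Fit a bone-density encoder
#'
#' @param records case records.
#' @param bd_type `"forearm"` or `"dual_femur"`.
#' @return an encoder object.
#' @export
fit_bone_density_encoder <- function(records, bd_type = c("forearm", "dual_femur")) {
  bd_type <- match.arg(bd_type)
  validate_records(records)
  structure(
    list(view = paste0("bd_", bd_type), bd_type = bd_type),
    class = c("bone_density_encoder", "melmv_encoder")
  )
}

#' Apply a fitted encoder to case records
#'
#' @param encoder a fitted `melmv_encoder`.
#' @param records case records.
#' @return a [view_matrix()].
#' @export
encode <- function(encoder, records) UseMethod("encode")

#' @export
encode.demographics_encoder <- function(encoder, records) {
  validate_records(records)
  race <- records$race
  unseen <- !(race %in% RACE_LEVELS)
  if (any(unseen)) {
    warning("unseen race level(s) mapped to other_unknown: ",
            paste(unique(race[unseen]), collapse = ", "), call. = FALSE)
    race[unseen] <- "other_unknown"
  }
  sd_use <- if (encoder$age_sd > 0) encoder$age_sd else 1
  vals <- cbind(age_z = (records$age - encoder$age_mean) / sd_use,
                sex_female = as.numeric(records$sex == "female"))
  for (lv in setdiff(RACE_LEVELS, RACE_REFERENCE)) {
    vals <- cbind(vals, as.numeric(race == lv))
    colnames(vals)[ncol(vals)] <- paste0("race_", lv)
  }
  view_matrix("demographics", vals, rep(TRUE, nrow(records)))
}

#' @export
encode.diagnosis_encoder <- function(encoder, records) {
  validate_records(records)
  vals <- matrix(0, nrow(records), length(encoder$categories),
                 dimnames = list(NULL, paste0("dx_", encoder$categories)))
  for (i in seq_len(nrow(records))) {
    cats <- suppressWarnings(
      collapse_icd9(records$diagnosis_codes[[i]], encoder$category_level))
    hit <- match(cats, encoder$categories)
    vals[i, hit[!is.na(hit)]] <- 1
  }
  view_matrix("diagnoses", vals, rep(TRUE, nrow(records)))
}

#' @export
encode.procedure_encoder <- function(encoder, records) {
  validate_records(records)
  vals <- matrix(0, nrow(records), length(encoder$codes),
                 dimnames = list(NULL, paste0("px_", encoder$codes)))
  n_codes <- integer(nrow(records))
  for (i in seq_len(nrow(records))) {
    codes <- unique(records$procedure_codes[[i]])
    n_codes[i] <- length(codes)
    hit <- match(codes, encoder$codes)
    vals[i, hit[!is.na(hit)]] <- 1
  }
  avail <- if (encoder$absent_as_missing) n_codes > 0L else rep(TRUE, nrow(records))
  view_matrix("procedures", vals, avail)
}

#' @export
encode.bone_density_encoder <- function(encoder, records) {
  validate_records(records)
  col <- paste0("bd_", encoder$bd_type)
  meas <- records[[col]]
  avail <- !vapply(meas, is.null, TRUE)
  vals <- matrix(NA_real_, nrow(records), 2, dimnames = list(NULL, c("bmd", "t_score")))
  vals[avail, ] <- t(vapply(meas[avail], function(m) m[c("bmd", "t_score")],
                            numeric(2)))
  view_matrix(col, vals, avail)
}

#' Encode a full cohort into the canonical five views
#'
#' Fits all encoders on `records` and transforms them, returning both the
#' dataset and the fitted encoders for reuse on new cases.
#'
#' @param records case records.
#' @param category_level ICD-9 category stem length.
#' @param absent_as_missing procedure-view availability rule.
#' @return list with `dataset` (a [multiview_dataset()]) and `encoders`.
#' @export
encode_cohort <- function(records, category_level = 3L, absent_as_missing = TRUE) {
  validate_records(records)
  encoders <- list(
    demographics = fit_demographics_encoder(records),
    diagnoses = fit_diagnosis_encoder(records, category_level),
    procedures = fit_procedure_encoder(records, absent_as_missing),
    bd_forearm = fit_bone_density_encoder(records, "forearm"),
    bd_dual_femur = fit_bone_density_encoder(records, "dual_femur")
  )
  views <- lapply(encoders, encode, records = records)
  dataset <- multiview_dataset(records$case_id,
                               harm_to_label(records$harm_score, records$case_id),
                               views, harm_scores = records$harm_score)
  list(dataset = dataset, encoders = encoders)
}

#' Apply previously fitted encoders to new case records
#'
#' @param encoders the `encoders` element returned by [encode_cohort()].
#' @param records new case records.
#' @return a [multiview_dataset()] in the training feature space.
#' @export
apply_encoders <- function(encoders, records) {
  views <- lapply(encoders, encode, records = records)
  multiview_dataset(records$case_id,
                    harm_to_label(records$harm_score, records$case_id),
                    views, harm_scores = records$harm_score)
}
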