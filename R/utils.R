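# Internal helpers shared across modules.

sigmoid <- function(x) stats::plogis(x)

#' Derive a component seed from a run seed
#'
#' All randomness in a run flows from one integer seed; components (fold
#' assignment, imputation draws, generator stages) each get a deterministic
#' derived seed so that adding a stage never perturbs another stage's stream.
#'
#' @param seed integer run seed.
#' @param tag character label of the consuming component.
#' @return an integer seed below 2^31.
#' @keywords internal
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  codes <- utf8ToInt(tag)
  h <- sum(codes * seq_along(codes))
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729) %% (.Machine$integer.max - 1) + 1)
}

# Validate a binary 0/1 label vector with both classes present.
check_labels <- function(labels, require_both = TRUE) {
  if (!all(labels %in% c(0, 1))) {
    stop("labels must be coded 0/1 (1 = severe fall)", call. = FALSE)
  }
  if (require_both && (sum(labels == 1) == 0L || sum(labels == 0) == 0L)) {
    stop("both label classes must be present", call. = FALSE)
  }
  as.integer(labels)
}

#' Stratified fold assignment
#'
#' Assigns each case to one of `k` folds, separately within each label class,
#' so every fold carries (near-)proportional prevalence.
#'
#' @param labels binary 0/1 vector.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer vector of fold ids in `1:k`.
#' @export
stratified_folds <- function(labels, k, seed) {
  labels <- check_labels(labels)
  n_min <- min(sum(labels == 1), sum(labels == 0))
  if (n_min < k) {
    stop(sprintf(
      "cannot stratify %d-fold with only %d cases in the rarer class; use at most %d folds",
      k, n_min, n_min
    ), call. = FALSE)
  }
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in c(0L, 1L)) {
    idx <- which(labels == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

# Fast (penalty-free) logistic fit on a numeric matrix; returns coefficient
# vector (intercept first). NA coefficients from collinearity are zeroed.
logistic_fit <- function(x, y) {
  x <- cbind(`(Intercept)` = 1, x)
  fit <- suppressWarnings(stats::glm.fit(x, y, family = stats::binomial()))
  cf <- fit$coefficients
  cf[!is.finite(cf)] <- 0
  cf
}

logistic_predict <- function(coefs, x) {
  as.numeric(sigmoid(cbind(1, x) %*% coefs))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
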