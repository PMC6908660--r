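# Small in-code fixtures.

# Hand-built case records covering the encoder edge cases.
toy_records <- function() {
  rec <- data.frame(
    case_id = c("a1", "a2", "a3", "a4"),
    age = c(70, 55, 63, 80),
    sex = c("female", "male", "female", "male"),
    race = c("caucasian", "black", "asian", "caucasian"),
    harm_score = c(7L, 2L, 6L, 1L),
    stringsAsFactors = FALSE
  )
  rec$diagnosis_codes <- list(c("428.0", "428.21", "401.9"), c("250.00"),
                              character(0), c("428.1"))
  rec$procedure_codes <- list(c("C0010"), character(0), c("C0010", "C0020"),
                              character(0))
  rec$bd_forearm <- list(NULL, c(bmd = 0.5, t_score = -1.2), NULL, NULL)
  rec$bd_dual_femur <- list(c(bmd = 0.6, t_score = -0.4), NULL, NULL, NULL)
  rec
}

# A separable two-feature view with labels.
toy_separable <- function(n = 40) {
  y <- rep(c(0L, 1L), each = n / 2)
  x <- cbind(f1 = y * 2 + seq(0, 0.4, length.out = n),
             f2 = stats::rnorm(n, 0, 0.01))
  list(view = view_matrix("toy", x, rep(TRUE, n)), labels = y)
}

# A small meta-feature table: column "signal" tracks the labels, the others
# are pure noise.
toy_meta <- function(n = 200, n_noise = 3, seed = 1) {
  set.seed(seed)
  y <- c(0, 1, stats::rbinom(n - 2, 1, 0.4))
  tab <- data.frame(signal = plogis(3 * (y - 0.5) + stats::rnorm(n, 0, 0.8)))
  for (j in seq_len(n_noise)) tab[[paste0("noise", j)]] <- stats::runif(n)
  structure(list(table = tab, labels = y,
                 case_ids = sprintf("c%03d", seq_len(n)),
                 columns = data.frame(name = names(tab),
                                      view = NA, inducer = NA, kind = "score"),
                 flag_views = character(0)),
            class = "meta_features")
}
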