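# Independent brute-force oracles. These deliberately recompute everything
# from first principles (explicit loops, materialized pairwise matrices) and
# share no code path with the package implementation.

# Exhaustive midpoint-cutoff search for the Youden-optimal threshold:
# evaluates sensitivity + specificity naively at every candidate.
oracle_youden <- function(scores, labels) {
  u <- sort(unique(scores))
  cand <- if (length(u) == 1L) u else
    unique(pmin(1, pmax(0, c(0, (u[-length(u)] + u[-1]) / 2, 1))))
  J <- vapply(cand, function(t) {
    mean(scores[labels == 1] >= t) + mean(scores[labels == 0] < t)
  }, 0)
  cand[which(J == max(J))[1L]]
}

# Pairwise comparison statistic: mean over all positive-negative pairs of
# 1[s+ > s-] + 0.5 * 1[s+ == s-].
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

# DeLong variance from the explicitly materialized pairwise indicator matrix.
oracle_delong_var <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  psi <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  v10 <- rowMeans(psi)
  v01 <- colMeans(psi)
  stats::var(v10) / length(pos) + stats::var(v01) / length(neg)
}

# Random score/label instance with optional ties (scores on a coarse grid).
random_instance <- function(n, tie_prob = 0.5) {
  labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
  scores <- if (stats::runif(1) < tie_prob) {
    sample(seq(0, 1, by = 0.1), n, replace = TRUE)
  } else {
    stats::runif(n)
  }
  list(scores = scores, labels = labels)
}
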