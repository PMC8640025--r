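# Independent oracles used across the suite. These deliberately use naive
# loop-based formulations so they share no code with the implementation.

# Schafer-Strimmer shrinkage intensity, direct transcription of the
# published formula with explicit loops over feature pairs.
oracle_shrinkage_intensity <- function(X) {
  # X: standardized (mean 0, sd 1 with n-1 denominator)
  n <- nrow(X); p <- ncol(X)
  num <- 0; den <- 0
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      w <- X[, i] * X[, j]
      r <- sum(w) / (n - 1)
      v <- n / (n - 1)^3 * sum((w - mean(w))^2)
      num <- num + 2 * v
      den <- den + 2 * r^2
    }
  }
  min(1, max(0, num / den))
}

# PR-AUC by explicit enumeration of every rank threshold (step-function
# summation over the recall increments).
oracle_pr_auc <- function(scores, truth) {
  o <- order(-abs(scores), seq_along(scores))
  truth <- truth[o]
  s <- sum(truth)
  area <- 0
  prev_recall <- 0
  tp <- 0
  for (k in seq_along(truth)) {
    tp <- tp + truth[k]
    recall <- tp / s
    precision <- tp / k
    area <- area + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  area
}

# Closed-form fractional power of the 2x2 compound-symmetry matrix
# [[1, rho], [rho, 1]]: eigenvalues 1 +/- rho with fixed eigenvectors.
oracle_cs2_power <- function(rho, e) {
  l1 <- (1 + rho)^e; l2 <- (1 - rho)^e
  matrix(c((l1 + l2) / 2, (l1 - l2) / 2,
           (l1 - l2) / 2, (l1 + l2) / 2), 2, 2)
}

# Small standardized random design for parameterised tests.
rand_fm <- function(n, p, seed) {
  set.seed(seed)
  standardize(matrix(rnorm(n * p), n, p))
}
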