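# Independent oracles and random-input generators shared across tests.
# These deliberately avoid the package's own code paths.

# Sort-and-tally rank probabilities: per draw, sort the effects and read
# each treatment's position off the sorted vector. Tie-free draws only.
oracle_rank_probs <- function(draws, larger_better = TRUE) {
  s <- if (larger_better) draws else -draws
  l <- ncol(s)
  tally <- matrix(0, l, l)
  for (d in seq_len(nrow(s))) {
    sorted <- sort(s[d, ], decreasing = TRUE)
    for (i in seq_len(l)) {
      b <- which(sorted == s[d, i])[1L]
      tally[i, b] <- tally[i, b] + 1
    }
  }
  tally / nrow(s)
}

# Random doubly stochastic matrix: convex mixture of permutation matrices
# (Birkhoff), exactly doubly stochastic up to float rounding.
random_doubly_stochastic <- function(l, k = 6L) {
  w <- stats::rexp(k); w <- w / sum(w)
  P <- matrix(0, l, l)
  for (m in seq_len(k)) {
    perm <- sample.int(l)
    P <- P + w[m] * diag(l)[perm, , drop = FALSE]
  }
  P
}

# Random antisymmetric comparison estimates with symmetric positive SEs.
random_estimates <- function(l, outcome = "o") {
  est <- matrix(0, l, l)
  est[upper.tri(est)] <- stats::rnorm(l * (l - 1) / 2, sd = 2)
  est <- est - t(est)
  se <- matrix(0, l, l)
  se[upper.tri(se)] <- stats::runif(l * (l - 1) / 2, 0.2, 2)
  se <- se + t(se)
  comparison_estimates(est, se, paste0("t", seq_len(l)), outcome = outcome)
}

# Tie-free random effect draws.
random_samples <- function(l, n, direction = "larger_better") {
  effect_samples(matrix(stats::rnorm(n * l), n, l), paste0("t", seq_len(l)),
                 outcome = "o", direction = direction)
}

# Consistent versus-reference estimate set under which independent
# resampling and the analytic P-score target the same quantity.
reference_consistent_estimates <- function(l, outcome = "o") {
  d <- c(0, stats::rnorm(l - 1, sd = 1.5))
  v <- c(0, stats::runif(l - 1, 0.3, 1.5)^2)
  comparison_estimates(outer(d, d, `-`), sqrt(outer(v, v, `+`)),
                       paste0("t", seq_len(l)), outcome = outcome)
}

# The spec fixture everyone shares: the published lumbar-fusion summary.
fixture_table <- function(metric = "p_score") lumbar_fusion_table(metric)

count_matches <- function(lines, pattern) {
  sum(vapply(gregexpr(pattern, lines, fixed = TRUE),
             function(m) sum(m > 0), numeric(1L)))
}
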