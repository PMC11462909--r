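test_that("rank probabilities tally draws correctly", {
  # single treatment always ranks first
  s1 <- effect_samples(matrix(rnorm(5), 5, 1), "only")
  expect_equal(unname(rank_probabilities(s1)$P), matrix(1))

  # strict dominance
  s2 <- effect_samples(cbind(a = c(3, 5, 4), b = c(1, 2, 0)))
  P2 <- rank_probabilities(s2)$P
  expect_equal(unname(P2), rbind(c(1, 0), c(0, 1)))

  # hand-tallied 4-draw case: draws sorted independently, ranks counted
  draws <- rbind(c(0.1, 0.2, 0.3), c(0.3, 0.2, 0.1),
                 c(0.2, 0.3, 0.1), c(0.3, 0.1, 0.2))
  P3 <- rank_probabilities(effect_samples(draws, c("A", "B", "C")))$P
  expect_equal(unname(P3[, 1]), c(0.50, 0.25, 0.25))
  expect_equal(unname(P3), oracle_rank_probs(draws))
})

test_that("rank probability errors and tie handling", {
  expect_error(effect_samples(matrix(numeric(0), 0, 2)), "no draws")
  expect_error(effect_samples(matrix(1:4, 2, 2), c("A", "A")),
               "duplicate treatment")
  tied <- effect_samples(rbind(c(1, 1), c(2, 1)))
  expect_error(rank_probabilities(tied), "ties")
  # seeded tie break keeps the matrix doubly stochastic and reproducible
  P1 <- rank_probabilities(tied, seed = 11)$P
  P2 <- rank_probabilities(tied, seed = 11)$P
  expect_identical(P1, P2)
  expect_equal(rowSums(P1), c(a = 1, b = 1), ignore_attr = TRUE)
  expect_equal(colSums(P1), c(1, 1), ignore_attr = TRUE)
})

test_that("rank matrices are doubly stochastic over randomized inputs", {
  set.seed(42)
  for (rep in 1:25) {
    l <- sample(2:6, 1)
    rpm <- rank_probabilities(random_samples(l, sample(10:200, 1)))
    expect_lt(max(abs(rowSums(rpm$P) - 1)), 1e-9)
    expect_lt(max(abs(colSums(rpm$P) - 1)), 1e-9)
    expect_true(all(rpm$P >= 0 & rpm$P <= 1))
  }
})

test_that("rank probabilities match the exhaustive oracle on small cases", {
  set.seed(7)
  for (rep in 1:100) {
    l <- sample(1:4, 1)
    n <- sample(1:6, 1)
    draws <- matrix(rnorm(n * l), n, l)
    dir <- sample(c("larger_better", "smaller_better"), 1)
    P <- rank_probabilities(effect_samples(draws, direction = dir))$P
    expect_equal(unname(P), oracle_rank_probs(draws, dir == "larger_better"))
  }
})

test_that("p_best extracts the first rank column", {
  P <- rbind(c(0.7, 0.2, 0.1), c(0.2, 0.5, 0.3), c(0.1, 0.3, 0.6))
  rpm <- as_rank_probability_matrix(P, c("A", "B", "C"))
  expect_equal(unname(p_best(rpm)$values), c(0.7, 0.2, 0.1))
  uni <- as_rank_probability_matrix(matrix(0.25, 4, 4), paste0("t", 1:4))
  expect_equal(unname(p_best(uni)$values), rep(0.25, 4))
  expect_equal(sum(p_best(rpm)$values), 1)
})

test_that("cumulative probabilities are running row sums", {
  P <- rbind(c(0.2, 0.3, 0.5), c(0.5, 0.3, 0.2), c(0.3, 0.4, 0.3))
  cum <- cumulative_probabilities(as_rank_probability_matrix(P, c("A", "B", "C")))
  expect_equal(unname(cum$C[1, ]), c(0.2, 0.5, 1.0))
  expect_equal(unname(cum$C[, 3]), rep(1, 3))
  expect_true(all(diff(t(cum$C)) >= -1e-12))
  # certain-first treatment: all-ones cumulative row
  cert <- as_rank_probability_matrix(rbind(c(1, 0), c(0, 1)), c("A", "B"))
  expect_equal(unname(cumulative_probabilities(cert)$C[1, ]), c(1, 1))
})

test_that("SUCRA follows the cumulative-surface formula", {
  # near-certain best among six: surface = 4.999 / 5
  P <- diag(6)
  P[1, ] <- c(0.999, 0.001, 0, 0, 0, 0)
  P[2, ] <- c(0.001, 0.999, 0, 0, 0, 0)
  su <- sucra(as_rank_probability_matrix(P, paste0("t", 1:6)))
  expect_equal(unname(su$values[1]), 4.999 / 5)
  expect_equal(round(unname(su$values[1]), 3), 1.000)

  # certain-last treatment scores 0
  cert_last <- as_rank_probability_matrix(rbind(c(0, 1), c(1, 0)), c("A", "B"))
  expect_equal(unname(sucra(cert_last)$values), c(0, 1))

  # uniform rank distribution gives 0.5 everywhere
  for (l in c(2, 4, 7)) {
    uni <- as_rank_probability_matrix(matrix(1 / l, l, l), paste0("t", 1:l))
    expect_equal(unname(sucra(uni)$values), rep(0.5, l))
  }

  # single treatment: convention 1 with a warning
  one <- as_rank_probability_matrix(matrix(1), "only")
  expect_warning(su1 <- sucra(one), "convention")
  expect_equal(unname(su1$values), 1)
})

test_that("SUCRA equals the rescaled mean rank on random matrices", {
  set.seed(99)
  for (rep in 1:50) {
    l <- sample(2:8, 1)
    rpm <- as_rank_probability_matrix(random_doubly_stochastic(l),
                                      paste0("t", 1:l))
    su <- sucra(rpm)$values
    er <- mean_rank(rpm)
    expect_equal(unname(su), unname((l - er) / (l - 1)), tolerance = 1e-12)
  }
})

test_that("SUCRA and P-score obey the l/2 conservation law", {
  set.seed(123)
  for (rep in 1:50) {
    l <- sample(2:8, 1)
    rpm <- as_rank_probability_matrix(random_doubly_stochastic(l),
                                      paste0("t", 1:l))
    expect_lt(abs(sum(sucra(rpm)$values) - l / 2), 1e-9)
    expect_lt(abs(sum(p_score(random_estimates(l))$values) - l / 2), 1e-9)
  }
})

test_that("P-score is the mean pairwise normal superiority probability", {
  # null comparison: both treatments at 0.5
  est0 <- comparison_estimates(matrix(0, 2, 2), matrix(1, 2, 2), c("A", "B"))
  expect_equal(unname(p_score(est0)$values), c(0.5, 0.5))

  # z = 1.96: 0.975 / 0.025
  z <- 1.959964
  est1 <- comparison_estimates(rbind(c(0, z), c(-z, 0)), matrix(1, 2, 2),
                               c("A", "B"))
  expect_equal(round(unname(p_score(est1)$values), 3), c(0.975, 0.025))

  # three treatments at (0, 1, 2), all pairwise se = 1
  d <- c(0, 1, 2)
  est2 <- comparison_estimates(outer(d, d, `-`), matrix(1, 3, 3),
                               c("A", "B", "C"))
  expect_equal(unname(p_score(est2)$values[3]), (pnorm(1) + pnorm(2)) / 2)

  # direction flip mirrors the scores
  est_s <- comparison_estimates(rbind(c(0, z), c(-z, 0)), matrix(1, 2, 2),
                                c("A", "B"), direction = "smaller_better")
  expect_equal(round(unname(p_score(est_s)$values), 3), c(0.025, 0.975))

  expect_error(comparison_estimates(matrix(0, 2, 2),
                                    matrix(c(0, -1, -1, 0), 2, 2),
                                    c("A", "B")),
               "nonpositive standard error")
})

test_that("two-treatment closed forms agree across metrics", {
  set.seed(5)
  for (rep in 1:20) {
    rpm <- rank_probabilities(random_samples(2, 50))
    su <- sucra(rpm)$values
    pb <- p_best(rpm)$values
    expect_equal(unname(su[1]), unname(rpm$P[1, 1]), tolerance = 1e-12)
    expect_equal(unname(pb[1]), unname(rpm$P[1, 1]), tolerance = 1e-12)
    d <- rnorm(1); s <- runif(1, 0.1, 2)
    est <- comparison_estimates(rbind(c(0, d), c(-d, 0)), matrix(s, 2, 2),
                                c("A", "B"))
    expect_equal(unname(p_score(est)$values[1]), pnorm(d / s),
                 tolerance = 1e-12)
  }
})

test_that("flipping direction and negating draws leaves metrics unchanged", {
  set.seed(31)
  for (rep in 1:10) {
    l <- sample(2:5, 1)
    m <- matrix(rnorm(40 * l), 40, l)
    a <- effect_samples(m, paste0("t", 1:l), direction = "larger_better")
    b <- effect_samples(-m, paste0("t", 1:l), direction = "smaller_better")
    expect_equal(rank_probabilities(a)$P, rank_probabilities(b)$P)
  }
})

test_that("resampled rank probabilities bridge estimates to draw machinery", {
  est <- comparison_estimates(rbind(c(0, 10), c(-10, 0)),
                              matrix(0.1, 2, 2), c("A", "B"))
  rpm <- resample_rank_probabilities(est, n_draws = 1000, seed = 3, quiet = TRUE)
  expect_equal(unname(rpm$P[1, 1]), 1)

  est0 <- comparison_estimates(matrix(0, 2, 2), matrix(1, 2, 2), c("A", "B"))
  rpm0 <- resample_rank_probabilities(est0, n_draws = 100000, seed = 4,
                                      quiet = TRUE)
  expect_lt(abs(rpm0$P[1, 1] - 0.5), 0.01)

  # SUCRA of resampled draws converges to the analytic P-score
  set.seed(8)
  est3 <- reference_consistent_estimates(3)
  rpm3 <- resample_rank_probabilities(est3, n_draws = 200000, seed = 9,
                                      quiet = TRUE)
  expect_lt(max(abs(sucra(rpm3)$values - p_score(est3)$values)), 0.01)

  expect_warning(resample_rank_probabilities(est0, 100, seed = 1),
                 "independence")
  expect_error(resample_rank_probabilities(est0, 100, seed = 1,
                                           reference = "Z", quiet = TRUE),
               "reference")
})
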