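#' Rank-probability matrix from effect draws
#'
#' For each draw, treatments are ordered best-to-worst according to the
#' outcome's direction of benefit; `P[i, b]` is the fraction of draws in
#' which treatment `i` attains rank `b` (rank 1 = best). Every row and
#' every column of the result sums to one: the matrix is doubly stochastic.
#'
#' Exact ties within a draw are broken by a seeded uniform-random
#' permutation of the tied block, which keeps ranks integer and preserves
#' double stochasticity in expectation; tied inputs are therefore
#' seed-dependent and a seed is required when ties occur.
#'
#' @param samples An [effect_samples] object.
#' @param seed Integer seed for tie breaking; may be omitted when the draws
#'   contain no exact ties.
#' @return An object of class `rank_probability_matrix` with elements
#'   `treatments`, `P` (an `l x l` matrix, rows = treatments, columns =
#'   ranks), `n_draws`, `outcome` and `direction`.
#' @export
#' @examples
#' s <- effect_samples(cbind(a = c(1, 3), b = c(2, 2.5)), outcome = "resp")
#' rank_probabilities(s)$P
rank_probabilities <- function(samples, seed = NULL) {
  if (!inherits(samples, "effect_samples")) {
    stop_validation("samples must be an effect_samples object")
  }
  score <- direction_sign(samples$direction) * samples$draws
  n <- nrow(score)
  l <- ncol(score)
  tie_rows <- which(apply(score, 1L, anyDuplicated) > 0L)
  if (length(tie_rows) && is.null(seed)) {
    stop_validation("draws contain exact ties; supply a seed for tie breaking")
  }
  # rank of i within a draw = 1 + number of strictly better competitors;
  # exact in tie-free rows, and tied rows are re-ranked below.
  rk <- matrix(1L, n, l)
  for (i in seq_len(l)) {
    for (j in seq_len(l)[-i]) rk[, i] <- rk[, i] + (score[, j] > score[, i])
  }
  if (length(tie_rows)) {
    tiebreak <- with_seed(seed, matrix(stats::runif(length(tie_rows) * l),
                                       length(tie_rows), l))
    for (k in seq_along(tie_rows)) {
      d <- tie_rows[k]
      ord <- order(-score[d, ], tiebreak[k, ])   # best first
      rk[d, ord] <- seq_len(l)
    }
  }
  counts <- vapply(seq_len(l), function(i) tabulate(rk[, i], nbins = l),
                   integer(l))
  P <- t(counts) / n
  dimnames(P) <- list(samples$treatments, paste0("rank", seq_len(l)))
  structure(
    list(treatments = samples$treatments, P = P, n_draws = n,
         outcome = samples$outcome, direction = samples$direction,
         seed = seed),
    class = "rank_probability_matrix"
  )
}

#' @export
print.rank_probability_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("Rank probabilities: outcome '%s', %d treatments, %d draws\n",
              x$outcome, length(x$treatments), x$n_draws))
  print(round(x$P, digits))
  invisible(x)
}

validate_rpm <- function(rpm, tol = 1e-9) {
  if (!inherits(rpm, "rank_probability_matrix")) {
    stop_validation("expected a rank_probability_matrix")
  }
  P <- rpm$P
  if (any(P < -tol | P > 1 + tol)) stop_validation("rank probabilities outside [0,1]")
  if (max(abs(rowSums(P) - 1)) > tol || max(abs(colSums(P) - 1)) > tol) {
    stop_validation("rank-probability matrix is not doubly stochastic")
  }
  invisible(rpm)
}

#' Wrap a bare doubly stochastic matrix as a rank-probability matrix
#'
#' For rank matrices obtained outside the package (e.g. published tables
#' or external NMA software). Double stochasticity is validated.
#'
#' @param P Square doubly stochastic matrix, rows = treatments,
#'   columns = ranks (rank 1 = best).
#' @param treatments Labels; default the row names of `P`.
#' @param outcome Outcome label.
#' @param direction Direction of benefit the ranks already encode.
#' @param n_draws Number of draws behind `P`, if known.
#' @return A `rank_probability_matrix`.
#' @export
as_rank_probability_matrix <- function(P, treatments = rownames(P),
                                       outcome = "outcome",
                                       direction = "larger_better",
                                       n_draws = NA_integer_) {
  treatments <- check_labels(treatments %||% paste0("trt", seq_len(nrow(P))))
  P <- as.matrix(P)
  dimnames(P) <- list(treatments, paste0("rank", seq_len(ncol(P))))
  rpm <- structure(
    list(treatments = treatments, P = P, n_draws = n_draws,
         outcome = outcome, direction = match_direction(direction),
         seed = NULL),
    class = "rank_probability_matrix"
  )
  validate_rpm(rpm)
}

#' Probability of being the best treatment
#'
#' Extracts `P(i = 1)`, the probability that each treatment ranks first,
#' from a rank-probability matrix. The values form a probability
#' distribution over treatments (they sum to one).
#'
#' @param rpm A `rank_probability_matrix`.
#' @return A [metric_vector] with metric `"p_best"`.
#' @export
p_best <- function(rpm) {
  validate_rpm(rpm)
  metric_vector(metric = "p_best",
                values = stats::setNames(rpm$P[, 1L], rpm$treatments),
                outcome = rpm$outcome)
}

#' Cumulative rank probabilities
#'
#' `C[i, b]` is the probability that treatment `i` ranks `b`-th or better,
#' the running row sum of the rank-probability matrix. Each row is
#' nondecreasing and ends at one.
#'
#' @param rpm A `rank_probability_matrix`.
#' @return An object of class `cumulative_rank_matrix`.
#' @export
cumulative_probabilities <- function(rpm) {
  validate_rpm(rpm)
  C <- t(apply(rpm$P, 1L, cumsum))
  if (ncol(rpm$P) == 1L) C <- matrix(C, ncol = 1L)  # apply() drops shape at l = 1
  dimnames(C) <- dimnames(rpm$P)
  structure(
    list(treatments = rpm$treatments, C = C, outcome = rpm$outcome,
         n_draws = rpm$n_draws),
    class = "cumulative_rank_matrix"
  )
}

#' @export
print.cumulative_rank_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("Cumulative rank probabilities: outcome '%s'\n", x$outcome))
  print(round(x$C, digits))
  invisible(x)
}

#' Surface under the cumulative ranking curve (SUCRA)
#'
#' \deqn{SUCRA_i = \frac{\sum_{b=1}^{l-1} P_{cum}(i, b)}{l - 1}}
#'
#' SUCRA is 1 for a treatment that is certainly best, 0 for one certainly
#' worst, and 0.5 for all treatments when ranks are uniform. It equals
#' `(l - E[rank_i]) / (l - 1)`, a rescaled mean rank. With a single
#' treatment the formula degenerates (division by zero); by convention the
#' sole treatment gets SUCRA 1 and a warning is emitted.
#'
#' @param x A `cumulative_rank_matrix` or a `rank_probability_matrix`
#'   (converted internally).
#' @return A [metric_vector] with metric `"sucra"`.
#' @export
#' @examples
#' P <- matrix(c(0.7, 0.3, 0.3, 0.7), 2, 2, dimnames = list(c("A", "B"), NULL))
#' sucra(as_rank_probability_matrix(P))
sucra <- function(x) UseMethod("sucra")

#' @export
sucra.rank_probability_matrix <- function(x) sucra(cumulative_probabilities(x))

#' @export
sucra.cumulative_rank_matrix <- function(x) {
  l <- ncol(x$C)
  vals <- if (l == 1L) {
    warning("single treatment: SUCRA defined as 1 by convention")
    stats::setNames(1, x$treatments)
  } else {
    stats::setNames(rowSums(x$C[, seq_len(l - 1L), drop = FALSE]) / (l - 1L),
                    x$treatments)
  }
  metric_vector(metric = "sucra", values = clamp_unit(vals), outcome = x$outcome)
}

#' Frequentist P-score
#'
#' The frequentist analogue of SUCRA: the mean one-sided probability, under
#' a normal approximation, that a treatment beats each competitor,
#' \deqn{P_i = \frac{1}{l-1} \sum_{j \ne i}
#'       \Phi\!\left(\frac{s \cdot \hat{d}_{ij}}{se_{ij}}\right)}
#' where \eqn{\Phi} is the standard normal CDF and `s` is +1 when larger
#' effects are better, -1 otherwise. Requires at least two treatments.
#'
#' @param est A [comparison_estimates] object.
#' @return A [metric_vector] with metric `"p_score"`.
#' @export
p_score <- function(est) {
  if (!inherits(est, "comparison_estimates")) {
    stop_validation("est must be a comparison_estimates object")
  }
  l <- length(est$treatments)
  if (l < 2L) stop_validation("P-score requires at least two treatments")
  s <- direction_sign(est$direction)
  z <- s * est$estimate / est$se
  diag(z) <- NA
  phi <- stats::pnorm(z)
  vals <- rowSums(phi, na.rm = TRUE) / (l - 1L)
  metric_vector(metric = "p_score",
                values = stats::setNames(vals, est$treatments),
                outcome = est$outcome)
}

#' Mean rank of each treatment
#'
#' `E[rank_i] = sum_b b * P[i, b]`; related to SUCRA through
#' `SUCRA_i = (l - E[rank_i]) / (l - 1)`.
#'
#' @param rpm A `rank_probability_matrix`.
#' @return Named numeric vector of expected ranks.
#' @export
mean_rank <- function(rpm) {
  validate_rpm(rpm)
  drop(rpm$P %*% seq_len(ncol(rpm$P)))
}

#' Rank probabilities from frequentist estimates by resampling
#'
#' Bridges estimate-based inputs to the draw-based ranking machinery:
#' effects versus a designated reference treatment are drawn from
#' independent normal distributions `N(estimate(i, ref), se(i, ref))`, the
#' reference fixed at zero, and the draws are passed to
#' [rank_probabilities()]. Covariance between comparisons is ignored
#' (independence approximation), which is flagged with a warning; with that
#' approximation the SUCRA of the result converges to the [p_score()] of
#' the same estimates as `n_draws` grows.
#'
#' @param est A [comparison_estimates] object.
#' @param n_draws Number of resampling draws (default 10000).
#' @param seed Integer seed; required, all draws are reproducible.
#' @param reference Reference treatment label; default the first treatment.
#' @param quiet Suppress the independence-approximation warning.
#' @return A `rank_probability_matrix`.
#' @export
resample_rank_probabilities <- function(est, n_draws = 10000, seed,
                                        reference = est$treatments[1L],
                                        quiet = FALSE) {
  if (!inherits(est, "comparison_estimates")) {
    stop_validation("est must be a comparison_estimates object")
  }
  if (missing(seed) || is.null(seed)) stop_validation("seed is required")
  n_draws <- as.integer(n_draws)
  if (is.na(n_draws) || n_draws < 1L) stop_validation("n_draws must be >= 1")
  ref <- match(reference, est$treatments)
  if (is.na(ref)) stop_validation("unknown reference treatment '%s'", reference)
  l <- length(est$treatments)
  mu <- est$estimate[, ref]
  sdv <- est$se[, ref]
  others <- setdiff(seq_len(l), ref)
  if (anyNA(mu[others]) || anyNA(sdv[others]) || any(sdv[others] <= 0)) {
    stop_validation("incomplete estimates versus reference")
  }
  if (!quiet) {
    warning("resampling assumes independence of comparisons versus '",
            reference, "' (no covariance supplied)")
  }
  draws <- matrix(0, n_draws, l)
  draws[, others] <- with_seed(seed, {
    matrix(stats::rnorm(n_draws * length(others),
                        mean = rep(mu[others], each = n_draws),
                        sd = rep(sdv[others], each = n_draws)),
           n_draws, length(others))
  })
  samples <- effect_samples(draws, est$treatments, outcome = est$outcome,
                            direction = est$direction)
  rpm <- rank_probabilities(samples, seed = seed)
  rpm$seed <- seed
  rpm
}
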