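#' Effect draws for one outcome
#'
#' Container for a draws-by-treatments matrix of relative effects on a
#' common scale, e.g. posterior MCMC samples or resampled frequentist
#' estimates. Each row is one draw; within a draw the treatments can be
#' ranked by effect size once the direction of benefit is known.
#'
#' @param draws Numeric matrix, `n_draws x l`; no missing values.
#' @param treatments Character vector of `l` unique treatment labels.
#'   Defaults to the column names of `draws`.
#' @param outcome Single outcome label.
#' @param direction `"larger_better"` or `"smaller_better"`; which end of
#'   the effect scale is clinically preferable. Never inferred from data.
#'
#' @return An object of class `effect_samples`.
#' @export
#' @examples
#' effect_samples(matrix(rnorm(20), 10, 2), c("A", "B"),
#'                outcome = "pain", direction = "smaller_better")
effect_samples <- function(draws, treatments = colnames(draws),
                           outcome = "outcome", direction = "larger_better") {
  direction <- match_direction(direction)
  draws <- as.matrix(draws)
  if (!is.numeric(draws)) stop_validation("draws must be numeric")
  if (nrow(draws) < 1L || ncol(draws) < 1L) stop_validation("no draws")
  if (anyNA(draws)) stop_validation("draws contain missing values")
  treatments <- check_labels(treatments %||% paste0("trt", seq_len(ncol(draws))))
  if (length(treatments) != ncol(draws)) {
    stop_validation("treatment labels (%d) do not match draw columns (%d)",
                    length(treatments), ncol(draws))
  }
  dimnames(draws) <- list(NULL, treatments)
  structure(
    list(outcome = as.character(outcome), treatments = treatments,
         draws = draws, direction = direction),
    class = "effect_samples"
  )
}

#' @export
print.effect_samples <- function(x, ...) {
  cat(sprintf("Effect samples: outcome '%s', %d draws x %d treatments (%s)\n",
              x$outcome, nrow(x$draws), length(x$treatments), x$direction))
  invisible(x)
}

#' Pairwise comparison estimates for one outcome
#'
#' Frequentist input: point estimates and standard errors for every pairwise
#' treatment comparison. Only antisymmetry of the estimates and symmetry and
#' positivity of the standard errors are validated; consistency of the full
#' pairwise set is the caller's responsibility.
#'
#' @param estimate Square numeric matrix, `estimate[i, j]` the relative
#'   effect of treatment `i` versus `j`; must satisfy
#'   `estimate[i, j] == -estimate[j, i]` within `1e-6`.
#' @param se Square numeric matrix of standard errors, symmetric with
#'   positive off-diagonal entries; the diagonal is ignored.
#' @param treatments Character labels, defaulting to matrix dimnames.
#' @param outcome Single outcome label.
#' @param direction `"larger_better"` or `"smaller_better"`.
#'
#' @return An object of class `comparison_estimates`.
#' @export
comparison_estimates <- function(estimate, se, treatments = colnames(estimate),
                                 outcome = "outcome",
                                 direction = "larger_better") {
  direction <- match_direction(direction)
  estimate <- as.matrix(estimate)
  se <- as.matrix(se)
  l <- ncol(estimate)
  if (nrow(estimate) != l || any(dim(se) != l)) {
    stop_validation("estimate and se must be square matrices of equal size")
  }
  treatments <- check_labels(treatments %||% paste0("trt", seq_len(l)))
  if (length(treatments) != l) stop_validation("treatment labels do not match matrix size")
  if (anyNA(estimate[row(estimate) != col(estimate)])) {
    stop_validation("missing pairwise estimates")
  }
  if (max(abs(estimate + t(estimate))) > 1e-6) {
    stop_validation("estimates violate antisymmetry: estimate(i,j) must equal -estimate(j,i)")
  }
  off <- se[row(se) != col(se)]
  if (anyNA(off) || any(off <= 0)) stop_validation("nonpositive standard error")
  if (max(abs(se - t(se))) > 1e-6) stop_validation("standard errors must be symmetric")
  diag(estimate) <- 0
  diag(se) <- 0
  dimnames(estimate) <- dimnames(se) <- list(treatments, treatments)
  structure(
    list(outcome = as.character(outcome), treatments = treatments,
         estimate = estimate, se = se, direction = direction),
    class = "comparison_estimates"
  )
}

#' @export
print.comparison_estimates <- function(x, ...) {
  cat(sprintf("Comparison estimates: outcome '%s', %d treatments (%s)\n",
              x$outcome, length(x$treatments), x$direction))
  invisible(x)
}
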