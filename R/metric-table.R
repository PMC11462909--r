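#' Per-treatment values of one ranking metric on one outcome
#'
#' @param metric One of `"p_best"`, `"sucra"`, `"p_score"`.
#' @param values Named numeric vector (names = treatments), all in `[0, 1]`.
#'   For `p_best` the values must sum to one.
#' @param outcome Single outcome label.
#' @return An object of class `metric_vector`.
#' @export
metric_vector <- function(metric, values, outcome = "outcome") {
  metric <- match.arg(metric, c("p_best", "sucra", "p_score"))
  treatments <- check_labels(names(values))
  values <- clamp_unit(as.numeric(values))
  if (anyNA(values) || any(values < 0 | values > 1)) {
    stop_validation("metric values must lie in [0, 1]")
  }
  if (metric == "p_best" && abs(sum(values) - 1) > 1e-9) {
    stop_validation("p_best values must sum to 1 (got %.6f)", sum(values))
  }
  structure(
    list(outcome = as.character(outcome), metric = metric,
         values = stats::setNames(values, treatments)),
    class = "metric_vector"
  )
}

#' @export
print.metric_vector <- function(x, digits = 3, ...) {
  cat(sprintf("%s on outcome '%s':\n", x$metric, x$outcome))
  print(round(x$values, digits))
  invisible(x)
}

#' Long-format metric table
#'
#' The three-column contract the beading plot consumes: one row per
#' (treatment, outcome) pair, `metric` holding the ranking-metric value in
#' `[0, 1]`. Row order is semantic: it drives the outcome-line and legend
#' ordering of every plot built from the table.
#'
#' @param records Data frame with columns `treatment`, `metric` (numeric
#'   value in `[0, 1]`) and `outcome`.
#' @param metric_name Which ranking metric the values are
#'   (`"p_best"`, `"sucra"`, `"p_score"`), or any descriptive label.
#' @param provenance Free-text source note.
#' @return An object of class `metric_table` (a data frame).
#' @export
metric_table <- function(records, metric_name = "metric",
                         provenance = NULL) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  need <- c("treatment", "metric", "outcome")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop_validation("missing column '%s'", miss[1L])
  if (nrow(records) == 0L) stop_validation("no records")
  records$treatment <- as.character(records$treatment)
  records$outcome <- as.character(records$outcome)
  if (!is.numeric(records$metric)) stop_validation("metric column must be numeric")
  bad <- which(is.na(records$metric) | records$metric < 0 | records$metric > 1)
  if (length(bad)) {
    stop_validation("metric out of range [0, 1] in row(s) %s",
                    paste(bad, collapse = ", "))
  }
  key <- paste(records$treatment, records$outcome, sep = "\r")
  if (anyDuplicated(key)) {
    stop_validation("duplicate (treatment, outcome) pair in row(s) %s",
                    paste(which(duplicated(key)), collapse = ", "))
  }
  out <- records[, need]
  rownames(out) <- NULL
  structure(out, metric_name = as.character(metric_name)[1L],
            provenance = provenance,
            class = c("metric_table", "data.frame"))
}

#' @export
print.metric_table <- function(x, ...) {
  cat(sprintf("Metric table (%s): %d records, %d treatments, %d outcomes\n",
              attr(x, "metric_name"), nrow(x),
              length(unique(x$treatment)), length(unique(x$outcome))))
  print.data.frame(x, ...)
  invisible(x)
}

#' Assemble a metric table from per-outcome metric vectors
#'
#' Stacks one [metric_vector] per outcome into the long three-column format.
#' All vectors must carry the same metric kind; values are copied unchanged.
#'
#' @param vectors List of [metric_vector] objects (or a single one).
#' @param provenance Optional source note.
#' @return A [metric_table].
#' @export
build_metric_table <- function(vectors, provenance = NULL) {
  if (inherits(vectors, "metric_vector")) vectors <- list(vectors)
  if (!length(vectors)) stop_validation("no metric vectors supplied")
  if (!all(vapply(vectors, inherits, logical(1L), "metric_vector"))) {
    stop_validation("all elements must be metric_vector objects")
  }
  kinds <- unique(vapply(vectors, function(v) v$metric, character(1L)))
  if (length(kinds) > 1L) {
    stop_validation("mixed metrics in one table: %s", paste(kinds, collapse = ", "))
  }
  rows <- do.call(rbind, lapply(vectors, function(v) {
    data.frame(treatment = names(v$values), metric = unname(v$values),
               outcome = v$outcome, stringsAsFactors = FALSE)
  }))
  metric_table(rows, metric_name = kinds, provenance = provenance)
}
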