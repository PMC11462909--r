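# CSV dialect is fixed throughout: UTF-8, comma separator, "." decimal,
# header mandatory. Readers reject rather than coerce: no value clipping,
# no NA imputation. Row order is semantic and preserved.

read_csv_strict <- function(path) {
  if (!file.exists(path)) stop_validation("file not found: %s", path)
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                    fileEncoding = "UTF-8"),
    error = function(e) stop_validation("cannot parse CSV %s: %s",
                                        path, conditionMessage(e))
  )
  df
}

#' Read a long-format metric table
#'
#' Expects columns `treatment`, `metric` (the ranking-metric value in
#' `[0, 1]`) and `outcome`, plus an optional `metric_name` column naming
#' the metric kind. Rows are validated (range, duplicate pairs) and row
#' order is preserved, since it drives plot ordering downstream.
#'
#' @param path CSV file path.
#' @param metric_name Metric-kind label; overrides any `metric_name`
#'   column in the file.
#' @return A [metric_table].
#' @export
read_metric_table <- function(path, metric_name = NULL) {
  df <- read_csv_strict(path)
  need <- c("treatment", "metric", "outcome")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_validation("missing column '%s' in %s", miss[1L], path)
  if (nrow(df) == 0L) stop_validation("no records in %s", path)
  if (!is.numeric(df$metric)) {
    stop_validation("non-numeric metric values in %s", path)
  }
  name <- metric_name %||%
    (if ("metric_name" %in% names(df)) unique(df$metric_name) else "metric")
  if (length(name) != 1L) {
    stop_validation("mixed metrics in one table: %s", paste(name, collapse = ", "))
  }
  metric_table(df[, need], metric_name = name, provenance = path)
}

#' Write a metric table to CSV
#'
#' Values are written at full double precision so that
#' `read_metric_table()` recovers the table exactly; display rounding
#' happens only in rendered labels.
#'
#' @param table A [metric_table].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_metric_table <- function(table, path) {
  stopifnot(inherits(table, "metric_table"))
  out <- data.frame(treatment = table$treatment,
                    metric = fmt_num(table$metric),
                    outcome = table$outcome,
                    metric_name = attr(table, "metric_name"),
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a matrix of effect draws
#'
#' Header row of treatment labels, one row per draw; rectangular, numeric,
#' no missing cells.
#'
#' @param path CSV file path.
#' @param direction `"larger_better"` or `"smaller_better"` (mandatory;
#'   direction of benefit is never inferred).
#' @param outcome Outcome label; defaults to the file name without
#'   extension.
#' @return An [effect_samples] object.
#' @export
read_effect_samples <- function(path, direction,
                                outcome = sub("\\.[^.]*$", "", basename(path))) {
  df <- read_csv_strict(path)
  if (nrow(df) == 0L) stop_validation("no draws in %s", path)
  notnum <- names(df)[!vapply(df, is.numeric, logical(1L))]
  if (length(notnum)) {
    bad <- which(is.na(suppressWarnings(as.numeric(df[[notnum[1L]]]))))[1L]
    stop_validation("non-numeric cell in column '%s', data row %s of %s",
                    notnum[1L], bad %||% "?", path)
  }
  m <- as.matrix(df)
  if (anyNA(m)) {
    stop_validation("missing value at data row %s of %s",
                    which(rowSums(is.na(m)) > 0)[1L], path)
  }
  effect_samples(m, treatments = names(df), outcome = outcome,
                 direction = direction)
}

#' Read pairwise comparison estimates
#'
#' Two layouts are accepted:
#' \describe{
#'   \item{pairwise}{columns `treatment1,treatment2,estimate,se`, one row
#'     per ordered or unordered pair; antisymmetry is validated when both
#'     orderings are present.}
#'   \item{versus-reference}{columns `treatment,estimate,se`; the reference
#'     row has estimate 0 and se 0. The full pairwise set is completed
#'     assuming consistency, `estimate(i,j) = estimate(i,ref) -
#'     estimate(j,ref)`, with the independence approximation
#'     `se(i,j)^2 = se(i,ref)^2 + se(j,ref)^2` (a warning notes the
#'     approximation).}
#' }
#'
#' @param path CSV file path.
#' @param direction `"larger_better"` or `"smaller_better"`.
#' @param outcome Outcome label; defaults to the file name.
#' @param quiet Suppress the independence-approximation warning.
#' @return A [comparison_estimates] object.
#' @export
read_comparison_estimates <- function(path, direction,
                                      outcome = sub("\\.[^.]*$", "", basename(path)),
                                      quiet = FALSE) {
  df <- read_csv_strict(path)
  if (all(c("treatment1", "treatment2", "estimate", "se") %in% names(df))) {
    return(estimates_from_pairwise(df, direction, outcome, path))
  }
  if (all(c("treatment", "estimate", "se") %in% names(df))) {
    return(estimates_from_reference(df, direction, outcome, path, quiet))
  }
  stop_validation(paste0(
    "unknown estimates layout in %s: expected columns ",
    "treatment1,treatment2,estimate,se or treatment,estimate,se"), path)
}

estimates_from_pairwise <- function(df, direction, outcome, path) {
  trts <- unique(c(df$treatment1, df$treatment2))
  l <- length(trts)
  est <- matrix(NA_real_, l, l, dimnames = list(trts, trts))
  se <- matrix(NA_real_, l, l, dimnames = list(trts, trts))
  diag(est) <- 0; diag(se) <- 0
  for (r in seq_len(nrow(df))) {
    i <- match(df$treatment1[r], trts); j <- match(df$treatment2[r], trts)
    if (i == j) stop_validation("self-comparison at row %d of %s", r, path)
    if ((!is.na(est[i, j]) && abs(est[i, j] - df$estimate[r]) > 1e-6) ||
        (!is.na(est[j, i]) && abs(est[j, i] + df$estimate[r]) > 1e-6)) {
      stop_validation("antisymmetry violated (conflicting comparison) at row %d of %s",
                      r, path)
    }
    est[i, j] <- df$estimate[r];  est[j, i] <- -df$estimate[r]
    se[i, j] <- se[j, i] <- df$se[r]
  }
  if (anyNA(est)) stop_validation("incomplete pairwise comparisons in %s", path)
  comparison_estimates(est, se, trts, outcome = outcome, direction = direction)
}

estimates_from_reference <- function(df, direction, outcome, path, quiet) {
  refrow <- which(df$estimate == 0 & df$se == 0)
  if (length(refrow) != 1L) {
    stop_validation("versus-reference layout needs exactly one reference row (estimate 0, se 0) in %s",
                    path)
  }
  trts <- df$treatment
  l <- length(trts)
  if (l < 2L) stop_validation("need at least two treatments in %s", path)
  if (any(df$se[-refrow] <= 0)) stop_validation("nonpositive standard error in %s", path)
  if (!quiet) {
    warning("deriving pairwise standard errors under the independence ",
            "approximation se(i,j)^2 = se(i,ref)^2 + se(j,ref)^2")
  }
  d <- df$estimate
  v <- df$se^2
  est <- outer(d, d, `-`)
  se <- sqrt(outer(v, v, `+`))
  comparison_estimates(est, se, trts, outcome = outcome, direction = direction)
}

#' Packaged lumbar-fusion ranking summary
#'
#' The worked example shipped with the package: ranking metrics for six
#' lumbar-fusion techniques over four outcomes (fusion rate, Oswestry
#' Disability Index, adverse events, operative time), as published in the
#' source network meta-analysis summary. Transcribed verbatim, including a
#' known anomaly: the ODI p_best column duplicates the p_score column and
#' sums to 2.0 rather than 1 (flagged in the file's comment column), so
#' `metric = "p_best"` data from the ODI block must not be treated as a
#' probability distribution.
#'
#' @param metric Which metric column to extract: `"p_score"` (default),
#'   `"sucra"` or `"p_best"`.
#' @return A [metric_table] with 21 records (6 + 4 + 6 + 5 treatments over
#'   the four outcomes).
#' @export
#' @examples
#' tab <- lumbar_fusion_table("p_score")
#' nrow(tab)
lumbar_fusion_table <- function(metric = c("p_score", "sucra", "p_best")) {
  metric <- match.arg(metric)
  path <- system.file("extdata", "table1_lumbar_fusion.csv",
                      package = "beadrank", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  metric_table(
    data.frame(treatment = df$treatment, metric = df[[metric]],
               outcome = df$outcome, stringsAsFactors = FALSE),
    metric_name = metric, provenance = path
  )
}
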