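# Companion ranking graphics share one scene container: `kind` selects the
# geometry, `payload` holds the kind-specific elements, and `fingerprint`
# ties the scene back to the exact numbers it was built from.

companion_scene <- function(kind, payload, fingerprint) {
  structure(list(schema_version = "1", kind = kind, payload = payload,
                 fingerprint = fingerprint),
            class = "companion_scene")
}

fingerprint_of <- function(labels, values) {
  list(n = length(values), labels = as.list(labels),
       checksum = fmt_num(sum(values)))
}

#' @export
print.companion_scene <- function(x, ...) {
  cat(sprintf("Companion scene: kind '%s'\n", x$kind))
  invisible(x)
}

#' Bar chart of a global ranking metric
#'
#' One bar per treatment, sorted by metric descending so the best
#' treatment is leftmost; ties are ordered alphabetically.
#'
#' @param vec A [metric_vector].
#' @return A `companion_scene` of kind `metric_bars`.
#' @export
build_metric_bar_chart <- function(vec) {
  if (!inherits(vec, "metric_vector")) stop_validation("vec must be a metric_vector")
  ord <- order(-vec$values, names(vec$values))
  bars <- lapply(ord, function(i) {
    list(treatment = names(vec$values)[i], value = unname(vec$values[i]))
  })
  companion_scene("metric_bars",
                  list(metric_name = vec$metric, outcome = vec$outcome,
                       bars = bars),
                  fingerprint_of(names(vec$values)[ord], vec$values[ord]))
}

#' Rank-probability charts
#'
#' Displays the full rank-probability matrix: per-treatment panels of bars
#' or lines over ranks 1..l (`"bars"`, `"lines"`), a single stacked bar per
#' treatment partitioned by rank (`"stacked_bars"`), or all treatments
#' overlaid on one panel (`"multi_line"`). The most probable rank of a
#' treatment is its highest peak / largest segment.
#'
#' @param rpm A `rank_probability_matrix`.
#' @param kind One of `"bars"`, `"lines"`, `"stacked_bars"`, `"multi_line"`.
#' @return A `companion_scene`.
#' @export
build_rank_probability_chart <- function(rpm, kind = c("bars", "lines",
                                                       "stacked_bars",
                                                       "multi_line")) {
  kind <- match.arg(kind)
  validate_rpm(rpm)
  l <- ncol(rpm$P)
  series <- lapply(seq_along(rpm$treatments), function(i) {
    list(treatment = rpm$treatments[i], values = as.list(unname(rpm$P[i, ])))
  })
  payload <- list(outcome = rpm$outcome, ranks = as.list(seq_len(l)),
                  series = series)
  companion_scene(paste0("rank_prob_", kind), payload,
                  fingerprint_of(rpm$treatments, rowSums(rpm$P * seq_len(l)[col(rpm$P)])))
}

#' Cumulative ranking curves
#'
#' One nondecreasing curve per treatment from `C[i, 1]` up to 1; as
#' per-treatment panels or a single overlaid multi-line chart. The best
#' candidates are those reaching 100% cumulative probability earliest; the
#' area under the curve over ranks 1..l-1, divided by l-1, is the
#' treatment's SUCRA.
#'
#' @param cum A `cumulative_rank_matrix`.
#' @param kind `"panels"` or `"multi_line"`.
#' @return A `companion_scene`.
#' @export
build_cumulative_chart <- function(cum, kind = c("panels", "multi_line")) {
  kind <- match.arg(kind)
  if (!inherits(cum, "cumulative_rank_matrix")) {
    stop_validation("cum must be a cumulative_rank_matrix")
  }
  series <- lapply(seq_along(cum$treatments), function(i) {
    list(treatment = cum$treatments[i], values = as.list(unname(cum$C[i, ])))
  })
  companion_scene(paste0("cumulative_", kind),
                  list(outcome = cum$outcome,
                       ranks = as.list(seq_len(ncol(cum$C))), series = series),
                  fingerprint_of(cum$treatments, cum$C[, 1L]))
}

#' Spie chart of one treatment across outcomes
#'
#' Each outcome is an equal-angle sector (angle `2*pi/k`); the sector
#' radius is `sqrt(value)` of the unit radius, so sector area is
#' proportional to the metric. Outcomes missing the treatment are omitted
#' with a message.
#'
#' @param table A [metric_table].
#' @param treatment Treatment label to display.
#' @return A `companion_scene` of kind `spie`.
#' @export
build_spie_chart <- function(table, treatment) {
  if (!inherits(table, "metric_table")) table <- metric_table(table)
  outcomes <- unique(table$outcome)
  sel <- table[table$treatment == treatment, , drop = FALSE]
  if (nrow(sel) == 0L) stop_validation("unknown treatment '%s'", treatment)
  absent <- setdiff(outcomes, sel$outcome)
  if (length(absent)) {
    message("treatment '", treatment, "' absent for outcome(s): ",
            paste(absent, collapse = ", "), "; sectors omitted")
  }
  k <- nrow(sel)
  angle <- 2 * pi / k
  sectors <- lapply(seq_len(k), function(i) {
    list(outcome = sel$outcome[i], value = sel$metric[i],
         start_angle = (i - 1) * angle, end_angle = i * angle,
         radius = sqrt(sel$metric[i]))
  })
  companion_scene("spie",
                  list(treatment = treatment,
                       metric_name = attr(table, "metric_name"),
                       sectors = sectors,
                       omitted_outcomes = as.list(absent)),
                  fingerprint_of(sel$outcome, sel$metric))
}

#' Heat plot of metrics over outcomes and treatments
#'
#' A grid of outcomes (rows) by treatments (columns); cell color maps
#' linearly from the metric value over `[0, 1]` along a cool-to-warm ramp
#' (0 = coolest blue, 1 = warmest red). Missing (treatment, outcome)
#' combinations are explicit empty cells.
#'
#' @param table A [metric_table].
#' @return A `companion_scene` of kind `heat`.
#' @export
build_heat_plot <- function(table) {
  if (!inherits(table, "metric_table")) table <- metric_table(table)
  outcomes <- unique(table$outcome)
  treatments <- unique(table$treatment)
  key <- paste(table$treatment, table$outcome, sep = "\r")
  cells <- list()
  for (o in outcomes) {
    for (t in treatments) {
      i <- match(paste(t, o, sep = "\r"), key)
      cells[[length(cells) + 1L]] <- if (is.na(i)) {
        list(outcome = o, treatment = t, empty = TRUE)
      } else {
        list(outcome = o, treatment = t, empty = FALSE,
             value = table$metric[i], color = heat_ramp(table$metric[i]))
      }
    }
  }
  companion_scene("heat",
                  list(metric_name = attr(table, "metric_name"),
                       outcomes = as.list(outcomes),
                       treatments = as.list(treatments), cells = cells),
                  fingerprint_of(key, table$metric))
}

# Linear cool-to-warm ramp over [0, 1] (endpoints: #313695 -> #A50026).
heat_ramp <- function(v) {
  ramp <- grDevices::colorRamp(c("#313695", "#FFFFBF", "#A50026"))
  rgb <- ramp(v)
  grDevices::rgb(rgb[, 1L], rgb[, 2L], rgb[, 3L], maxColorValue = 255)
}
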