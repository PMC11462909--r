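# Palettes are pure data: the treatment -> color map must be a pure
# function of the ordered treatment list, so scenes rebuild identically.
beadrank_palettes <- list(
  # 12 distinguishable categorical hues
  default = c("#1F77B4", "#FF7F0E", "#2CA02C", "#D62728", "#9467BD",
              "#8C564B", "#E377C2", "#7F7F7F", "#BCBD22", "#17BECF",
              "#AA3377", "#4477AA"),
  # Okabe-Ito color-blind-safe scheme
  colorblind = c("#E69F00", "#56B4E9", "#009E73", "#F0E442", "#0072B2",
                 "#D55E00", "#CC79A7", "#999999", "#000000")
)

rob_border_colors <- c(low = "#2CA02C", some = "#E6C229", high = "#D62728")

palette_colors <- function(palette, n) {
  cols <- beadrank_palettes[[palette]]
  if (is.null(cols)) stop_validation("unknown palette '%s'", palette)
  if (n > length(cols)) {
    warning(sprintf(
      "%d treatments exceed the %d hues of palette '%s'; colors recycle - consider top_k filtering",
      n, length(cols), palette))
  }
  rep_len(cols, n)
}

#' Build a beading-plot scene
#'
#' The beading plot is a number-line graphic: one horizontal line per
#' outcome spanning the closed interval \[0, 1\], with one colored bead per
#' treatment placed exactly at its ranking-metric value (SUCRA, P-score or
#' P-best). Treatments keep a single color across all outcome lines,
#' matched in the legend. The scene returned is renderer-independent; pass
#' it to [render()] for SVG/PNG or [write_scene_json()] to serialize.
#'
#' Beads are never moved off their exact x-position. When beads on one line
#' fall closer together than `overlap_threshold`, only their text labels
#' dodge: labels alternate above/below the line in order of x within the
#' crowded cluster, and clusters of more than four labels switch to
#' leader-line placement.
#'
#' @param table A [metric_table]; all values in `[0, 1]`, one metric kind.
#' @param palette `"default"` (12 hues) or `"colorblind"` (Okabe-Ito).
#' @param top_k Keep only the `k` best treatments per outcome
#'   (`NULL` = keep all; the published default when enabled is 5).
#' @param reverse_x Mirror the axis so 1 is on the left.
#' @param sort_outcomes `"input"` (first appearance, default),
#'   `"alphabetical"`, or `"by_treatment"` (descending metric of
#'   `sort_treatment`).
#' @param sort_treatment Treatment label used when
#'   `sort_outcomes = "by_treatment"`.
#' @param risk_of_bias Optional data frame with columns `outcome` and
#'   `level` (`"low"`, `"some"`, `"high"`) drawn as a colored border
#'   segment next to each outcome line.
#' @param overlap_threshold Minimum x-distance between beads on one line
#'   before labels start dodging (axis units; default 0.03).
#' @return An object of class `beading_scene`.
#' @export
#' @examples
#' tab <- lumbar_fusion_table("p_score")
#' sc <- build_beading_plot(tab)
#' length(sc$lines)
build_beading_plot <- function(table, palette = c("default", "colorblind"),
                               top_k = NULL, reverse_x = FALSE,
                               sort_outcomes = c("input", "alphabetical",
                                                 "by_treatment"),
                               sort_treatment = NULL,
                               risk_of_bias = NULL,
                               overlap_threshold = 0.03) {
  palette <- match.arg(palette)
  sort_outcomes <- match.arg(sort_outcomes)
  if (!inherits(table, "metric_table")) {
    table <- metric_table(table)
  }
  if (any(table$metric < 0 | table$metric > 1)) {
    stop_validation("metric out of range")
  }
  if (!is.null(top_k)) {
    top_k <- as.integer(top_k)
    if (is.na(top_k) || top_k < 1L) stop_validation("top_k must be >= 1")
    keep <- unlist(lapply(split(seq_len(nrow(table)), table$outcome), function(idx) {
      ord <- idx[order(-table$metric[idx], table$treatment[idx])]
      utils::head(ord, top_k)
    }), use.names = FALSE)
    table <- table[sort(keep), , drop = FALSE]
  }

  outcomes <- unique(table$outcome)
  outcomes <- switch(sort_outcomes,
    input = outcomes,
    alphabetical = sort(outcomes),
    by_treatment = {
      if (is.null(sort_treatment)) {
        stop_validation("sort_treatment required when sort_outcomes = \"by_treatment\"")
      }
      sel <- table[table$treatment == sort_treatment, ]
      if (nrow(sel) == 0L) stop_validation("unknown treatment '%s'", sort_treatment)
      val <- stats::setNames(sel$metric, sel$outcome)[outcomes]
      outcomes[order(-ifelse(is.na(val), -Inf, val))]
    })
  treatments <- unique(table$treatment)
  colors <- palette_colors(palette, length(treatments))

  lines <- lapply(seq_along(outcomes), function(i) {
    list(outcome = outcomes[i], level = i)
  })
  beads <- lapply(seq_len(nrow(table)), function(r) {
    trt <- table$treatment[r]
    list(outcome = table$outcome[r], treatment = trt,
         x = table$metric[r], color = colors[match(trt, treatments)],
         label = trt, label_side = "above", label_slot = 1L,
         leader = FALSE)
  })
  beads <- dodge_labels(beads, overlap_threshold)

  border <- NULL
  if (!is.null(risk_of_bias)) {
    rob <- as.data.frame(risk_of_bias, stringsAsFactors = FALSE)
    if (!all(c("outcome", "level") %in% names(rob))) {
      stop_validation("risk_of_bias needs columns 'outcome' and 'level'")
    }
    if (!all(rob$level %in% names(rob_border_colors))) {
      stop_validation("risk-of-bias levels must be low/some/high")
    }
    rob <- rob[rob$outcome %in% outcomes, , drop = FALSE]
    border <- lapply(seq_len(nrow(rob)), function(r) {
      list(outcome = rob$outcome[r], level = rob$level[r],
           color = unname(rob_border_colors[rob$level[r]]))
    })
  }

  structure(
    list(schema_version = "1",
         metric_name = attr(table, "metric_name") %||% "metric",
         axis = list(min = 0, max = 1, ticks = as.list(seq(0, 1, by = 0.25)),
                     reversed = isTRUE(reverse_x)),
         palette = palette,
         lines = lines,
         beads = beads,
         legend = lapply(seq_along(treatments), function(i) {
           list(treatment = treatments[i], color = colors[i])
         }),
         border = border),
    class = "beading_scene"
  )
}

# Alternate label sides within clusters of near-coincident beads; leave
# bead x untouched. Clusters > 4 get leader-line labels.
dodge_labels <- function(beads, threshold) {
  if (!length(beads)) return(beads)
  outc <- vapply(beads, function(b) b$outcome, character(1L))
  for (o in unique(outc)) {
    idx <- which(outc == o)
    ord <- idx[order(vapply(beads[idx], function(b) b$x, numeric(1L)))]
    xs <- vapply(beads[ord], function(b) b$x, numeric(1L))
    cluster <- cumsum(c(1, diff(xs) > threshold))
    for (cl in unique(cluster)) {
      members <- ord[cluster == cl]
      use_leader <- length(members) > 4L
      for (k in seq_along(members)) {
        i <- members[k]
        beads[[i]]$label_side <- if (k %% 2L == 1L) "above" else "below"
        beads[[i]]$label_slot <- as.integer(ceiling(k / 2))
        beads[[i]]$leader <- use_leader
      }
    }
  }
  beads
}

#' @export
print.beading_scene <- function(x, ...) {
  cat(sprintf(
    "Beading scene (%s): %d outcome lines, %d beads, %d treatments%s\n",
    x$metric_name, length(x$lines), length(x$beads), length(x$legend),
    if (x$axis$reversed) ", reversed axis" else ""))
  invisible(x)
}

#' Invert the beading-plot axis transform
#'
#' Maps a rendered pixel x-coordinate back to the metric value, given the
#' scene's axis and the plotting window used by the renderer. Exposed so
#' positional fidelity is checkable: `axis_invert(scene, axis_project(...))`
#' recovers the value.
#'
#' @param scene A `beading_scene`.
#' @param px Pixel coordinate(s).
#' @param x0,x1 Pixel positions of metric 0 and 1 (renderer margins).
#' @return Metric value(s).
#' @export
axis_invert <- function(scene, px, x0, x1) {
  v <- (px - x0) / (x1 - x0)
  if (scene$axis$reversed) 1 - v else v
}

axis_project <- function(scene, value, x0, x1) {
  v <- if (scene$axis$reversed) 1 - value else value
  x0 + v * (x1 - x0)
}
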