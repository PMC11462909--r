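# Rendering. SVG output is emitted directly as SVG 1.1 markup from the
# scene description with fixed coordinate formatting, so a given scene
# always produces byte-identical SVG; fonts are referenced by family name,
# never embedded. PNG output goes through the grDevices png device using
# the plot() methods below.

svg_num <- function(x) sprintf("%.4f", x)

svg_open <- function(width, height) {
  c('<?xml version="1.0" encoding="UTF-8"?>',
    sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" ',
                   'width="%d" height="%d" viewBox="0 0 %d %d" ',
                   'font-family="Helvetica, Arial, sans-serif">'),
            width, height, width, height))
}

svg_text <- function(x, y, s, size = 11, anchor = "start", fill = "#000000") {
  sprintf('<text x="%s" y="%s" font-size="%d" text-anchor="%s" fill="%s">%s</text>',
          svg_num(x), svg_num(y), size, anchor, fill, xml_escape(s))
}

xml_escape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  gsub(">", "&gt;", s, fixed = TRUE)
}

#' Render a scene to SVG or PNG
#'
#' @param scene A `beading_scene` or `companion_scene`.
#' @param path Output file path.
#' @param format `"svg"` (deterministic markup) or `"png"` (raster via the
#'   png device).
#' @param width,height Pixel dimensions for PNG; SVG sizes itself from the
#'   scene.
#' @return `path`, invisibly.
#' @export
#' @examples
#' sc <- build_beading_plot(lumbar_fusion_table())
#' f <- tempfile(fileext = ".svg")
#' render(sc, f, "svg")
render <- function(scene, path, format = c("svg", "png"),
                   width = 900, height = 600) {
  if (length(format) == 1L && !format %in% c("svg", "png")) {
    stop_validation("unknown format '%s'", format)
  }
  format <- match.arg(format)
  if (format == "svg") {
    markup <- if (inherits(scene, "beading_scene")) {
      beading_svg(scene)
    } else if (inherits(scene, "companion_scene")) {
      companion_svg(scene)
    } else {
      stop_validation("cannot render object of class '%s'", class(scene)[1L])
    }
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(markup, con, sep = "\n", useBytes = TRUE)
  } else {
    grDevices::png(path, width = width, height = height)
    on.exit(grDevices::dev.off())
    graphics::plot(scene)
  }
  invisible(path)
}

# ---- beading plot ---------------------------------------------------------

beading_layout <- function(scene) {
  n <- length(scene$lines)
  list(x0 = 70, x1 = 640, band = 90, top = 30,
       width = 840, height = 30 + n * 90 + 60)
}

beading_svg <- function(scene) {
  ly <- beading_layout(scene)
  out <- svg_open(ly$width, ly$height)
  axis_y <- ly$top + length(scene$lines) * ly$band + 25
  # axis with ticks
  out <- c(out, sprintf('<line class="axis" x1="%s" y1="%s" x2="%s" y2="%s" stroke="#000000"/>',
                        svg_num(ly$x0), svg_num(axis_y), svg_num(ly$x1), svg_num(axis_y)))
  for (tk in unlist(scene$axis$ticks)) {
    tx <- axis_project(scene, tk, ly$x0, ly$x1)
    out <- c(out,
             sprintf('<line class="tick" x1="%s" y1="%s" x2="%s" y2="%s" stroke="#000000"/>',
                     svg_num(tx), svg_num(axis_y), svg_num(tx), svg_num(axis_y + 5)),
             svg_text(tx, axis_y + 18, sprintf("%.2f", tk), anchor = "middle"))
  }
  out <- c(out, svg_text((ly$x0 + ly$x1) / 2, axis_y + 36, scene$metric_name,
                         size = 12, anchor = "middle"))
  line_y <- function(level) ly$top + (level - 0.5) * ly$band
  for (ln in scene$lines) {
    y <- line_y(ln$level)
    out <- c(out,
             sprintf('<line class="outcome-line" x1="%s" y1="%s" x2="%s" y2="%s" stroke="#555555" stroke-width="1.5"/>',
                     svg_num(ly$x0), svg_num(y), svg_num(ly$x1), svg_num(y)),
             svg_text(ly$x0 - 8, y + 4, ln$outcome, anchor = "end"))
  }
  if (!is.null(scene$border)) {
    levels <- vapply(scene$lines, function(l) l$level,
                     numeric(1L))
    names(levels) <- vapply(scene$lines, function(l) l$outcome, character(1L))
    for (bd in scene$border) {
      y <- line_y(levels[[bd$outcome]])
      out <- c(out, sprintf('<rect class="rob-border" x="6" y="%s" width="6" height="%s" fill="%s"/>',
                            svg_num(y - ly$band / 2 + 5), svg_num(ly$band - 10),
                            bd$color))
    }
  }
  level_of <- stats::setNames(vapply(scene$lines, function(l) l$level, numeric(1L)),
                              vapply(scene$lines, function(l) l$outcome, character(1L)))
  for (bd in scene$beads) {
    y <- line_y(level_of[[bd$outcome]])
    cx <- axis_project(scene, bd$x, ly$x0, ly$x1)
    dy <- (bd$label_slot - 1L) * 12 + if (isTRUE(bd$leader)) 24 else 14
    label_y <- if (identical(bd$label_side, "above")) y - dy else y + dy + 8
    if (isTRUE(bd$leader)) {
      out <- c(out, sprintf('<line class="leader" x1="%s" y1="%s" x2="%s" y2="%s" stroke="#999999" stroke-width="0.5"/>',
                            svg_num(cx), svg_num(y), svg_num(cx), svg_num(label_y - 4)))
    }
    out <- c(out,
             sprintf('<circle class="bead" cx="%s" cy="%s" r="6" fill="%s" stroke="#222222" stroke-width="0.5"/>',
                     svg_num(cx), svg_num(y), bd$color),
             svg_text(cx, label_y, bd$label, size = 9, anchor = "middle"))
  }
  lx <- ly$x1 + 30
  out <- c(out, svg_text(lx, ly$top + 10, "Treatment", size = 11))
  for (i in seq_along(scene$legend)) {
    en <- scene$legend[[i]]
    yy <- ly$top + 14 + i * 16
    out <- c(out,
             sprintf('<circle class="legend-swatch" cx="%s" cy="%s" r="5" fill="%s"/>',
                     svg_num(lx + 5), svg_num(yy - 4), en$color),
             svg_text(lx + 16, yy, en$treatment, size = 10))
  }
  c(out, "</svg>")
}

# ---- companion scenes -----------------------------------------------------

companion_svg <- function(scene) {
  switch(scene$kind,
    metric_bars = bars_svg(scene),
    heat = heat_svg(scene),
    spie = spie_svg(scene),
    series_svg(scene))
}

bars_svg <- function(scene) {
  bars <- scene$payload$bars
  n <- length(bars)
  w <- 80; gap <- 20; x0 <- 60; y0 <- 40; h <- 300
  out <- svg_open(x0 + n * (w + gap) + 40, y0 + h + 60)
  for (i in seq_len(n)) {
    b <- bars[[i]]
    bh <- b$value * h
    x <- x0 + (i - 1) * (w + gap)
    out <- c(out,
             sprintf('<rect class="bar" x="%s" y="%s" width="%s" height="%s" fill="#4477AA"/>',
                     svg_num(x), svg_num(y0 + h - bh), svg_num(w), svg_num(bh)),
             svg_text(x + w / 2, y0 + h + 16, b$treatment, size = 10,
                      anchor = "middle"),
             svg_text(x + w / 2, y0 + h - bh - 6, sprintf("%.3f", b$value),
                      size = 9, anchor = "middle"))
  }
  out <- c(out, svg_text(x0, y0 - 12, sprintf("%s (%s)",
                                              scene$payload$metric_name,
                                              scene$payload$outcome), size = 12))
  c(out, "</svg>")
}

heat_svg <- function(scene) {
  outs <- unlist(scene$payload$outcomes)
  trts <- unlist(scene$payload$treatments)
  cw <- 90; ch <- 44; x0 <- 140; y0 <- 70
  out <- svg_open(x0 + length(trts) * cw + 30, y0 + length(outs) * ch + 30)
  for (j in seq_along(trts)) {
    out <- c(out, svg_text(x0 + (j - 0.5) * cw, y0 - 10, trts[j], size = 10,
                           anchor = "middle"))
  }
  for (i in seq_along(outs)) {
    out <- c(out, svg_text(x0 - 8, y0 + (i - 0.5) * ch + 4, outs[i],
                           size = 10, anchor = "end"))
  }
  for (cell in scene$payload$cells) {
    i <- match(cell$outcome, outs); j <- match(cell$treatment, trts)
    x <- x0 + (j - 1) * cw; y <- y0 + (i - 1) * ch
    if (isTRUE(cell$empty)) {
      out <- c(out, sprintf('<rect class="cell empty" x="%s" y="%s" width="%s" height="%s" fill="none" stroke="#CCCCCC" stroke-dasharray="3,3"/>',
                            svg_num(x), svg_num(y), svg_num(cw - 2), svg_num(ch - 2)))
    } else {
      out <- c(out,
               sprintf('<rect class="cell" x="%s" y="%s" width="%s" height="%s" fill="%s" stroke="#FFFFFF"/>',
                       svg_num(x), svg_num(y), svg_num(cw - 2), svg_num(ch - 2),
                       cell$color),
               svg_text(x + cw / 2, y + ch / 2 + 4, sprintf("%.3f", cell$value),
                        size = 10, anchor = "middle", fill = "#FFFFFF"))
    }
  }
  c(out, "</svg>")
}

spie_svg <- function(scene) {
  R <- 150; cx <- 200; cy <- 190
  out <- svg_open(400, 400)
  out <- c(out, svg_text(cx, 24, sprintf("%s: %s", scene$payload$treatment,
                                         scene$payload$metric_name),
                         size = 12, anchor = "middle"))
  cols <- palette_colors("default", length(scene$payload$sectors))
  for (i in seq_along(scene$payload$sectors)) {
    sec <- scene$payload$sectors[[i]]
    r <- sec$radius * R
    a0 <- sec$start_angle - pi / 2   # start at 12 o'clock
    a1 <- sec$end_angle - pi / 2
    large <- if ((a1 - a0) > pi) 1 else 0
    d <- sprintf("M %s %s L %s %s A %s %s 0 %d 1 %s %s Z",
                 svg_num(cx), svg_num(cy),
                 svg_num(cx + r * cos(a0)), svg_num(cy + r * sin(a0)),
                 svg_num(r), svg_num(r), large,
                 svg_num(cx + r * cos(a1)), svg_num(cy + r * sin(a1)))
    am <- (a0 + a1) / 2
    out <- c(out,
             sprintf('<path class="sector" d="%s" fill="%s" stroke="#FFFFFF"/>', d, cols[i]),
             svg_text(cx + (R + 16) * cos(am), cy + (R + 16) * sin(am),
                      sec$outcome, size = 9, anchor = "middle"))
  }
  out <- c(out, sprintf('<circle class="spie-rim" cx="%s" cy="%s" r="%s" fill="none" stroke="#888888" stroke-dasharray="4,3"/>',
                        svg_num(cx), svg_num(cy), svg_num(R)))
  c(out, "</svg>")
}

# rank-probability and cumulative kinds share a line/bar-series geometry
series_svg <- function(scene) {
  series <- scene$payload$series
  ranks <- unlist(scene$payload$ranks)
  l <- length(ranks)
  stacked <- identical(scene$kind, "rank_prob_stacked_bars")
  multi <- grepl("multi_line$", scene$kind)
  cols <- palette_colors("default", length(series))
  if (stacked) {
    w <- 70; gap <- 24; x0 <- 60; y0 <- 40; h <- 300
    out <- svg_open(x0 + length(series) * (w + gap) + 160, y0 + h + 60)
    for (i in seq_along(series)) {
      s <- series[[i]]
      x <- x0 + (i - 1) * (w + gap)
      ybase <- y0 + h
      for (b in seq_len(l)) {
        seg <- s$values[[b]] * h
        out <- c(out, sprintf('<rect class="segment" x="%s" y="%s" width="%s" height="%s" fill="%s" stroke="#FFFFFF" stroke-width="0.5"/>',
                              svg_num(x), svg_num(ybase - seg), svg_num(w),
                              svg_num(seg), palette_colors("default", l)[b]))
        ybase <- ybase - seg
      }
      out <- c(out, svg_text(x + w / 2, y0 + h + 16, s$treatment, size = 10,
                             anchor = "middle"))
    }
    return(c(out, "</svg>"))
  }
  panel_w <- 220; panel_h <- 160
  ncol_p <- if (multi) 1L else min(3L, length(series))
  nrow_p <- if (multi) 1L else ceiling(length(series) / ncol_p)
  out <- svg_open(40 + ncol_p * (panel_w + 30), 40 + nrow_p * (panel_h + 40))
  draw_series <- function(s, ox, oy, color) {
    pts <- vapply(seq_len(l), function(b) {
      sprintf("%s,%s", svg_num(ox + (b - 1) / max(1, l - 1) * panel_w),
              svg_num(oy + panel_h - s$values[[b]] * panel_h))
    }, character(1L))
    sprintf('<polyline class="series" points="%s" fill="none" stroke="%s" stroke-width="1.5"/>',
            paste(pts, collapse = " "), color)
  }
  if (multi) {
    ox <- 40; oy <- 40
    out <- c(out, sprintf('<rect class="panel" x="%s" y="%s" width="%s" height="%s" fill="none" stroke="#888888"/>',
                          svg_num(ox), svg_num(oy), svg_num(panel_w), svg_num(panel_h)))
    for (i in seq_along(series)) {
      out <- c(out, draw_series(series[[i]], ox, oy, cols[i]))
    }
  } else {
    for (i in seq_along(series)) {
      r <- (i - 1) %/% ncol_p; cc <- (i - 1) %% ncol_p
      ox <- 40 + cc * (panel_w + 30); oy <- 40 + r * (panel_h + 40)
      out <- c(out,
               sprintf('<rect class="panel" x="%s" y="%s" width="%s" height="%s" fill="none" stroke="#888888"/>',
                       svg_num(ox), svg_num(oy), svg_num(panel_w), svg_num(panel_h)),
               draw_series(series[[i]], ox, oy, cols[i]),
               svg_text(ox + panel_w / 2, oy + panel_h + 16,
                        series[[i]]$treatment, size = 10, anchor = "middle"))
    }
  }
  c(out, "</svg>")
}

# ---- base-graphics plot methods (used for PNG and interactive use) --------

#' @export
plot.beading_scene <- function(x, ...) {
  n <- length(x$lines)
  graphics::par(mar = c(4, 8, 2, 8), xpd = NA)
  xlim <- if (x$axis$reversed) c(1, 0) else c(0, 1)
  graphics::plot(NA, xlim = xlim, ylim = c(n + 0.5, 0.5), yaxt = "n",
                 xlab = x$metric_name, ylab = "", bty = "n", ...)
  level_of <- stats::setNames(vapply(x$lines, function(l) l$level, numeric(1L)),
                              vapply(x$lines, function(l) l$outcome, character(1L)))
  for (ln in x$lines) {
    graphics::segments(0, ln$level, 1, ln$level, col = "grey40")
    graphics::mtext(ln$outcome, side = 2, at = ln$level, las = 1, line = 0.5,
                    cex = 0.8)
  }
  for (bd in x$beads) {
    y <- level_of[[bd$outcome]]
    graphics::points(bd$x, y, pch = 21, bg = bd$color, cex = 1.6)
    off <- (0.12 + 0.1 * (bd$label_slot - 1)) *
      if (identical(bd$label_side, "above")) -1 else 1
    graphics::text(bd$x, y + off, bd$label, cex = 0.6)
  }
  trts <- vapply(x$legend, function(e) e$treatment, character(1L))
  cols <- vapply(x$legend, function(e) e$color, character(1L))
  graphics::legend("topright", inset = c(-0.25, 0), legend = trts,
                   pt.bg = cols, pch = 21, bty = "n", cex = 0.8)
  invisible(x)
}

#' @export
plot.companion_scene <- function(x, ...) {
  p <- x$payload
  switch(x$kind,
    metric_bars = {
      vals <- vapply(p$bars, function(b) b$value, numeric(1L))
      names(vals) <- vapply(p$bars, function(b) b$treatment, character(1L))
      graphics::barplot(vals, ylim = c(0, 1), col = "#4477AA",
                        main = sprintf("%s (%s)", p$metric_name, p$outcome),
                        las = 2, ...)
    },
    heat = {
      outs <- unlist(p$outcomes); trts <- unlist(p$treatments)
      m <- matrix(NA_real_, length(outs), length(trts),
                  dimnames = list(outs, trts))
      for (cell in p$cells) {
        if (!isTRUE(cell$empty)) m[cell$outcome, cell$treatment] <- cell$value
      }
      graphics::image(seq_along(trts), seq_along(outs),
                      t(m)[, rev(seq_along(outs)), drop = FALSE],
                      col = heat_ramp(seq(0, 1, length.out = 64)),
                      zlim = c(0, 1), axes = FALSE, xlab = "", ylab = "",
                      main = p$metric_name, ...)
      graphics::axis(1, seq_along(trts), trts, las = 2)
      graphics::axis(2, seq_along(outs), rev(outs), las = 1)
    },
    spie = {
      graphics::par(mar = c(1, 1, 3, 1))
      graphics::plot(NA, xlim = c(-1.3, 1.3), ylim = c(-1.3, 1.3), asp = 1,
                     axes = FALSE, xlab = "", ylab = "",
                     main = sprintf("%s: %s", p$treatment, p$metric_name), ...)
      cols <- palette_colors("default", length(p$sectors))
      for (i in seq_along(p$sectors)) {
        sec <- p$sectors[[i]]
        th <- seq(sec$start_angle, sec$end_angle, length.out = 40) - pi / 2
        graphics::polygon(c(0, sec$radius * cos(th)),
                          c(0, -sec$radius * sin(th)), col = cols[i])
        am <- mean(th)
        graphics::text(1.15 * cos(am), -1.15 * sin(am), sec$outcome, cex = 0.7)
      }
    },
    { # series kinds
      series <- p$series
      l <- length(unlist(p$ranks))
      cols <- palette_colors("default", length(series))
      graphics::plot(NA, xlim = c(1, l), ylim = c(0, 1), xlab = "rank",
                     ylab = "probability", main = x$kind, ...)
      for (i in seq_along(series)) {
        graphics::lines(seq_len(l), unlist(series[[i]]$values), col = cols[i],
                        lwd = 2)
      }
      graphics::legend("topright",
                       legend = vapply(series, function(s) s$treatment,
                                       character(1L)),
                       col = cols, lwd = 2, bty = "n", cex = 0.7)
    })
  invisible(x)
}
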