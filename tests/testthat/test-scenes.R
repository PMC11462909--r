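test_that("beading scene mirrors the metric table exactly", {
  tab <- fixture_table("p_score")
  sc <- build_beading_plot(tab)
  expect_s3_class(sc, "beading_scene")
  expect_length(sc$lines, 4)
  expect_length(sc$legend, 6)
  expect_length(sc$beads, 21)
  # every bead sits at its table value, on an existing line
  line_outcomes <- vapply(sc$lines, `[[`, character(1), "outcome")
  for (i in seq_len(nrow(tab))) {
    bd <- sc$beads[[i]]
    expect_identical(bd$x, tab$metric[i])
    expect_true(bd$outcome %in% line_outcomes)
  }
  fr <- Filter(function(b) b$outcome == "fusion_rate" &&
                 b$treatment == "Circumferential", sc$beads)
  expect_equal(fr[[1]]$x, 0.999)
  # one color per treatment, everywhere
  colmap <- vapply(sc$legend, `[[`, character(1), "color")
  names(colmap) <- vapply(sc$legend, `[[`, character(1), "treatment")
  for (bd in sc$beads) expect_identical(bd$color, unname(colmap[bd$treatment]))
  expect_equal(sc$axis$min, 0)
  expect_equal(sc$axis$max, 1)
})

test_that("degenerate and invalid beading inputs", {
  one <- metric_table(data.frame(treatment = "A", metric = 0.5,
                                 outcome = "O1"), "sucra")
  sc <- build_beading_plot(one)
  expect_length(sc$lines, 1)
  expect_length(sc$beads, 1)
  expect_length(sc$legend, 1)
  expect_equal(sc$beads[[1]]$x, 0.5)
  expect_error(
    build_beading_plot(data.frame(treatment = "A", metric = 2, outcome = "o")),
    "range")
})

test_that("near-coincident beads keep exact x and dodge only labels", {
  tab <- metric_table(data.frame(treatment = c("A", "B"),
                                 metric = c(0.400, 0.404),
                                 outcome = "o"), "sucra")
  sc <- build_beading_plot(tab)
  xs <- vapply(sc$beads, `[[`, numeric(1), "x")
  expect_equal(sort(xs), c(0.400, 0.404))
  sides <- vapply(sc$beads, `[[`, character(1), "label_side")
  expect_setequal(sides, c("above", "below"))
  expect_false(any(vapply(sc$beads, `[[`, logical(1), "leader")))
  # a crowd of more than four switches to leader lines
  crowd <- metric_table(data.frame(treatment = paste0("t", 1:5),
                                   metric = 0.5 + (0:4) * 0.001,
                                   outcome = "o"), "sucra")
  sc5 <- build_beading_plot(crowd)
  expect_true(all(vapply(sc5$beads, `[[`, logical(1), "leader")))
  # well-separated beads all label above
  apart <- metric_table(data.frame(treatment = c("A", "B"),
                                   metric = c(0.1, 0.9), outcome = "o"),
                        "sucra")
  expect_true(all(vapply(build_beading_plot(apart)$beads, `[[`,
                         character(1), "label_side") == "above"))
})

test_that("beading options: palette, top-k, axis reversal, outcome order", {
  tab <- fixture_table()
  cb <- build_beading_plot(tab, palette = "colorblind")
  expect_identical(cb$palette, "colorblind")
  expect_false(identical(cb$legend[[1]]$color,
                         build_beading_plot(tab)$legend[[1]]$color))

  top <- build_beading_plot(tab, top_k = 5)
  fr <- Filter(function(b) b$outcome == "fusion_rate", top$beads)
  expect_length(fr, 5)
  dropped <- setdiff(
    tab$treatment[tab$outcome == "fusion_rate"],
    vapply(fr, `[[`, character(1), "treatment"))
  expect_identical(dropped, "PLF")  # lowest fusion-rate P-score is dropped

  rev <- build_beading_plot(tab, reverse_x = TRUE)
  expect_true(rev$axis$reversed)
  expect_equal(axis_invert(rev, axis_project(rev, 0.37, 70, 640), 70, 640),
               0.37, tolerance = 1e-9)

  alpha <- build_beading_plot(tab, sort_outcomes = "alphabetical")
  expect_identical(vapply(alpha$lines, `[[`, character(1), "outcome"),
                   sort(unique(tab$outcome)))

  rob <- build_beading_plot(tab, risk_of_bias = data.frame(
    outcome = c("ODI", "fusion_rate"), level = c("high", "low")))
  expect_length(rob$border, 2)
  expect_identical(rob$border[[1]]$color, "#D62728")
})

test_that("scene construction is a pure function of the table", {
  tab <- fixture_table()
  expect_identical(build_beading_plot(tab), build_beading_plot(tab))
  # positional fidelity: projecting then inverting recovers every value
  sc <- build_beading_plot(tab)
  for (bd in sc$beads) {
    expect_equal(axis_invert(sc, axis_project(sc, bd$x, 70, 640), 70, 640),
                 bd$x, tolerance = 1e-9)
  }
})

test_that("metric bar chart sorts descending with alphabetical ties", {
  v <- metric_vector("sucra", c(A = 0.2, B = 0.9, C = 0.5), "o")
  sc <- build_metric_bar_chart(v)
  expect_identical(vapply(sc$payload$bars, `[[`, character(1), "treatment"),
                   c("B", "C", "A"))
  tied <- metric_vector("sucra", c(C = 0.5, A = 0.5, B = 0.5), "o")
  expect_identical(vapply(build_metric_bar_chart(tied)$payload$bars, `[[`,
                          character(1), "treatment"),
                   c("A", "B", "C"))
  fr <- fixture_table()
  sel <- fr[fr$outcome == "fusion_rate", ]
  bars <- build_metric_bar_chart(
    metric_vector("p_score", setNames(sel$metric, sel$treatment),
                  "fusion_rate"))
  expect_identical(bars$payload$bars[[1]]$treatment, "Circumferential")
})

test_that("rank-probability and cumulative charts preserve the matrices", {
  P <- rbind(c(1, 0, 0), c(0, 0.4, 0.6), c(0, 0.6, 0.4))
  rpm <- as_rank_probability_matrix(P, c("A", "B", "C"))
  sc <- build_rank_probability_chart(rpm, "bars")
  expect_identical(sc$kind, "rank_prob_bars")
  expect_equal(unlist(sc$payload$series[[1]]$values), c(1, 0, 0))
  stacked <- build_rank_probability_chart(rpm, "stacked_bars")
  for (s in stacked$payload$series) {
    expect_equal(sum(unlist(s$values)), 1, tolerance = 1e-9)
  }
  uni <- as_rank_probability_matrix(matrix(0.25, 4, 4), paste0("t", 1:4))
  flat <- build_rank_probability_chart(uni, "multi_line")
  expect_true(all(abs(unlist(lapply(flat$payload$series, `[[`, "values")) -
                        0.25) < 1e-12))

  cum <- cumulative_probabilities(rpm)
  cc <- build_cumulative_chart(cum, "multi_line")
  for (s in cc$payload$series) {
    v <- unlist(s$values)
    expect_true(all(diff(v) >= -1e-12))
    expect_equal(v[length(v)], 1, tolerance = 1e-9)
  }
  # certain-first: constant at 1; certain-last: 0 until the final rank
  expect_equal(unlist(cc$payload$series[[1]]$values), c(1, 1, 1))
  # surface under each curve over ranks 1..l-1 reproduces SUCRA
  su <- sucra(cum)$values
  for (i in seq_along(cc$payload$series)) {
    v <- unlist(cc$payload$series[[i]]$values)
    expect_equal(sum(v[1:2]) / 2, unname(su[i]), tolerance = 1e-12)
  }
})

test_that("spie chart encodes metric as sector area", {
  tab <- fixture_table()
  expect_message(sc <- build_spie_chart(tab, "PLF"), NA)
  expect_length(sc$payload$sectors, 4)
  angles <- vapply(sc$payload$sectors,
                   function(s) s$end_angle - s$start_angle, numeric(1))
  expect_equal(angles, rep(pi / 2, 4))
  tab1 <- metric_table(data.frame(treatment = "A",
                                  metric = c(1, 0.25),
                                  outcome = c("o1", "o2")), "sucra")
  sc1 <- build_spie_chart(tab1, "A")
  expect_equal(vapply(sc1$payload$sectors, `[[`, numeric(1), "radius"),
               c(1, 0.5))
  # area proportionality: area = angle/2 * r^2 proportional to value
  areas <- vapply(sc1$payload$sectors,
                  function(s) (s$end_angle - s$start_angle) / 2 * s$radius^2,
                  numeric(1))
  vals <- vapply(sc1$payload$sectors, `[[`, numeric(1), "value")
  expect_equal(areas / areas[1], vals / vals[1], tolerance = 1e-9)
  # missing outcomes are omitted with a notice; unknown treatment errors
  expect_message(scx <- build_spie_chart(tab, "XLIF"), "omitted")
  expect_length(scx$payload$sectors, 3)
  expect_error(build_spie_chart(tab, "nosuch"), "unknown treatment")
})

test_that("heat plot grids outcomes by treatments with explicit empties", {
  tab <- fixture_table()
  sc <- build_heat_plot(tab)
  expect_length(sc$payload$cells, 24)  # 4 outcomes x 6 treatments
  empties <- Filter(function(c) isTRUE(c$empty), sc$payload$cells)
  expect_length(empties, 3)
  empty_keys <- vapply(empties, function(c) paste(c$outcome, c$treatment),
                       character(1))
  expect_setequal(empty_keys, c("ODI Circumferential", "ODI XLIF",
                                "operative_time Circumferential"))
  # ramp endpoints
  single <- metric_table(data.frame(treatment = "A", metric = 0,
                                    outcome = "o"), "sucra")
  expect_length(build_heat_plot(single)$payload$cells, 1)
  cold <- build_heat_plot(single)$payload$cells[[1]]$color
  hot <- build_heat_plot(metric_table(
    data.frame(treatment = "A", metric = 1, outcome = "o"),
    "sucra"))$payload$cells[[1]]$color
  expect_identical(toupper(cold), "#313695")
  expect_identical(toupper(hot), "#A50026")
})
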