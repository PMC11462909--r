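Package: beadrank
Title: Treatment-Ranking Metrics and Beading Plots for Network Meta-Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes treatment-ranking metrics for network meta-analysis
    (rank-probability matrices, P-best, cumulative rank probabilities,
    SUCRA, and the frequentist P-score) from posterior effect draws or from
    pairwise estimates with standard errors, and renders ranking graphics:
    the beading plot (a 0-1 number-line summary of rankings across multiple
    outcomes) together with the companion displays (rank-probability line
    and bar charts, cumulative ranking curves, heat plot, spie chart).
    Plots are built as renderer-independent scene objects that serialize
    losslessly to JSON and render deterministically to SVG or PNG. Includes
    a synthetic-scenario generator with known ground-truth rankings for
    parameter-recovery experiments, CSV readers and writers for effect
    samples, comparison estimates and long-format metric tables, and a
    command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
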