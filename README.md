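# beadrank

Treatment-ranking metrics and beading plots for network meta-analysis (NMA).

An NMA compares three or more treatments at once by pooling direct and
indirect evidence, and its output — a league table of pairwise effects per
outcome — is hard to act on. Ranking metrics compress it: from effect draws
(posterior MCMC samples or resampled frequentist estimates) one obtains the
rank-probability matrix *P(i = b)* (the probability that treatment *i*
attains rank *b*, rank 1 = best), and from it

- **P-best** = *P(i = 1)*, the probability of being the single best option;
- **SUCRA**, the surface under the cumulative ranking curve,
  `SUCRA_i = Σ_{b=1}^{l−1} P_cum(i, b) / (l − 1)`,
  where `P_cum(i, b)` is the probability of ranking *b*-th or better and
  *l* is the number of treatments (1 = certainly best, 0 = certainly worst,
  equivalently `(l − E[rank_i])/(l − 1)`);
- the **P-score**, the frequentist analogue: the mean one-sided probability
  under a normal approximation that a treatment beats each competitor,
  `P_i = (1/(l−1)) Σ_{j≠i} Φ(d̂_ij / se_ij)` (sign-adjusted for the
  direction of benefit).

The package computes all of these and draws the **beading plot**: one
horizontal 0–1 number line per outcome, with a colored bead per treatment
placed exactly at its metric value, so rankings across many outcomes are
readable at a glance. The companion displays (rank-probability line/bar
charts, cumulative ranking curves, heat plot, spie chart, sorted metric bar
chart) are included. Plots are built as renderer-independent *scenes* that
serialize losslessly to JSON and render deterministically to SVG or PNG —
the same inputs always produce byte-identical scene JSON and SVG.

It is intended for meta-analysts and methodologists who already have NMA
results (draws or estimates with standard errors) and need the ranking
layer: the NMA model itself is out of scope.

## Worked example

The packaged fixture transcribes a published ranking summary of six
lumbar-fusion techniques over four outcomes (fusion rate, Oswestry
Disability Index, adverse events, operative time):

```r
library(beadrank)
tab <- lumbar_fusion_table("p_score")
tab
#> Metric table (p_score): 21 records, 6 treatments, 4 outcomes
scene <- build_beading_plot(tab)
scene
#> Beading scene (p_score): 4 outcome lines, 21 beads, 6 treatments
render(scene, "bead.svg", "svg")
write_scene_json(scene, "bead.json")
```

The fusion-rate line carries a bead for circumferential fusion at
x = 0.999: it beats all competitors for that outcome almost surely, while
the adverse-event line shows the same treatment mid-field (0.548) — the
kind of trade-off the plot makes visible. Computing metrics from draws:

```r
s <- effect_samples(rbind(c(0.1, 0.2, 0.3), c(0.3, 0.2, 0.1),
                          c(0.2, 0.3, 0.1), c(0.3, 0.1, 0.2)),
                    c("A", "B", "C"))
rank_probabilities(s)$P
#>   rank1 rank2 rank3
#> A  0.50  0.25  0.25
#> B  0.25  0.50  0.25
#> C  0.25  0.25  0.50
sucra(rank_probabilities(s))$values
#>     A     B     C
#> 0.625 0.500 0.375
```

A command-line front end wraps the same functions
(`exec/beadrank metrics|bead|companion|simulate`); see the vignette.

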