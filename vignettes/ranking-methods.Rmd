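---
title: "Ranking metrics and beading plots: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking metrics and beading plots: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beadrank)
```

## The ranking problem

A network meta-analysis (NMA) yields relative effects for every pair of
treatments on every outcome. beadrank takes those results — not the trial
data — and answers the hierarchy question: *how do the treatments rank,
and how sure are we?* Two input forms are supported per outcome:

- **effect draws**: a matrix with one row per draw (posterior MCMC cycle
  or resampled estimate) and one column per treatment, all on one scale;
- **comparison estimates**: point estimates `d̂(i, j)` with standard
  errors for the pairwise comparisons, as frequentist NMA software
  reports them.

Every outcome carries a mandatory *direction of benefit*
(`larger_better` / `smaller_better`). It is never inferred from data:
silently guessing the direction is the costliest error this kind of
tooling can make, so omitting it is an error, not a default.

## From draws to metrics

Within each draw the treatments are sorted best-to-worst; tallying
positions over draws gives the rank-probability matrix `P[i, b]`,
which is doubly stochastic — each treatment has some rank, and each rank
is held by some treatment, so rows and columns both sum to one. This
invariant is asserted on every matrix the package builds or accepts.

From `P` follow P-best (`P[, 1]`), the cumulative matrix
`C[i, b] = Σ_{k≤b} P[i, k]`, and

$$\mathrm{SUCRA}_i \;=\; \frac{\sum_{b=1}^{l-1} C(i,b)}{l-1}
\;=\; \frac{l - E[\mathrm{rank}_i]}{l-1}.$$

The second identity (SUCRA as rescaled mean rank) is used as an internal
cross-check, and implies the conservation law `Σ_i SUCRA_i = l/2` for any
doubly stochastic matrix — a strong, cheap test that holds to machine
precision.

**P-score.** For frequentist inputs the package uses the standard
definition: the mean of one-sided pairwise superiority probabilities
under the normal approximation,
$P_i = \frac{1}{l-1}\sum_{j\neq i}\Phi(s\,\hat d_{ij}/se_{ij})$ with
`s = ±1` by direction. It satisfies the same `l/2` conservation law
because `Φ(x) + Φ(−x) = 1`.

**Bridging estimates to draws.** `resample_rank_probabilities()` makes
SUCRA and P-best available from frequentist inputs by drawing effects
versus a reference treatment from independent normals
`N(d̂(i, ref), se(i, ref))`. Ignoring the covariance between comparisons
is an approximation, so the function warns unless silenced. Under that
independence model the expected rank identity
`E[rank_i] = 1 + Σ_{j≠i} P(j beats i)` makes resampled SUCRA and analytic
P-score estimates of the same quantity; the test suite checks they agree
within 0.01 per treatment at 100,000 draws.

### Numerical choices

- **Ties.** Exact ties within a draw are broken by a seeded random
  permutation of the tied block. Mid-rank splitting would produce
  non-integer ranks and break the rank-tally semantics; random breaking
  preserves double stochasticity in expectation. Tied inputs are
  therefore seed-dependent, and calling without a seed on tied data is an
  error rather than a silent choice.
- **Degenerate sizes.** A single treatment is allowed everywhere it is
  meaningful: its rank matrix is `[[1]]`, and its SUCRA is defined as 1
  by convention (the formula divides by `l − 1`), with a warning, so
  pipelines over many outcomes do not crash on a one-treatment network.
- **Unit-interval hygiene.** Running sums can land a float epsilon above
  1; values within `1e-9` of the interval are snapped back, anything
  further is rejected. Readers never clip: an out-of-range value in a CSV
  is an error naming the row.
- **Precision vs display.** All values are kept at full double precision;
  CSV writers emit 17 significant digits so tables round-trip exactly.
  Rounding to 3 decimals happens only in rendered labels, matching the
  precision at which such summary tables are conventionally reported.
- **Seeds.** Every stochastic operation requires an explicit seed and
  records it; default `n_draws` is 10,000. The synthetic module splits
  one master seed into independent child seeds (one per operation), so
  adding an operation never perturbs earlier draws.

## The beading plot

A beading plot is a number-line graphic: one horizontal line per outcome
spanning `[0, 1]`, one bead per treatment at exactly its metric value,
one color per treatment across all lines, matched in the legend. The
scene built by `build_beading_plot()` is renderer-independent and
serializes canonically to JSON (serialize → parse → serialize is
byte-identical), which is what makes plot determinism testable.

Design choices where the layout was genuinely open:

- **Beads never move.** Positional accuracy is the plot's whole point, so
  crowded beads stay put and only their *labels* dodge: within a cluster
  of beads closer than `overlap_threshold` (default 0.03 axis units),
  labels alternate above/below the line in order of x; clusters of more
  than four switch to leader lines.
- **Axis direction.** x increases left to right, so the best treatment is
  rightmost; `reverse_x` mirrors it. (The "best on the left" convention
  applies to the sorted bar chart, not the number line.)
- **Ordering.** Outcome lines follow first appearance in the input table
  — row order is semantic throughout the package — with alphabetical or
  by-treatment sorting as options. Treatment colors are assigned by first
  appearance, making the color map a pure function of the table.
- **Palettes.** A 12-hue categorical default and an Okabe–Ito
  color-blind-safe alternative. Beyond the palette size colors recycle
  with a warning suggesting the `top_k` filter (keep the k best
  treatments per outcome; k = 5 when enabled), which is also the escape
  hatch for networks with many treatments.
- **Missing pairs.** A treatment absent on an outcome simply has no bead;
  the line still spans the full interval. The heat plot shows the same
  absence as an explicitly empty cell.
- **Risk-of-bias border.** An optional per-outcome categorical annotation
  (low/some/high → green/yellow/red border segment). The encoding is this
  package's own choice and is documented as such.

Companion scenes (rank-probability bars/lines/stacked bars, cumulative
curves, heat plot, spie chart, sorted metric bars) carry their source
values untransformed apart from the documented geometry mapping — e.g.
spie sector radius is `sqrt(value)` so sector *area* is proportional to
the metric, and stacked segments per treatment sum to one.

## The packaged example table

`lumbar_fusion_table()` ships a published ranking summary for six
lumbar-fusion techniques over four outcomes (6 + 4 + 6 + 5 = 21 records):
a real, moderately sparse multi-outcome structure for examples and
structural tests. It is transcribed verbatim, including one anomaly: the
ODI block's P-best column equals its P-score column and sums to 2.0, so
it cannot be a probability distribution over treatments. The file flags
those rows in a comment column, and the package excludes the ODI block
from P-best probability-sum checks rather than "correcting" published
numbers. Whether the table's SUCRA values came from Bayesian simulation
or frequentist resampling is not stated in the source and is not assumed
anywhere.

## What the synthetic scenarios do and do not show

`generate_scenario()` builds ranking problems with known truth: equally
spaced true effects `(0, g, …, (l−1)g)` — the simplest controllable
hierarchy; arbitrary vectors are accepted — and independent normal draws
with standard deviation `draw_sd`. `generate_estimates()` derives a
consistent pairwise estimate set from the same truth.
`recovery_experiment()` then measures how often the SUCRA ordering
reproduces the true ranking across a gap × noise grid: recovery reaches
1 under strong separation (gap/sd = 10) and falls to the permutation
chance level `1/l!` at zero gap, with monotone improvement in between
checked as a trend.

The generator emulates exactly one thing: exchangeable-noise ranking with
a known hierarchy. It does not simulate trial-level data, network
geometry, between-study heterogeneity, correlated multi-arm contrasts, or
inconsistency — so passing recovery tests validates the *metric and
plotting machinery*, not the upstream NMA. Validation sizes used by the
test suite and acceptance script: 1000 random doubly stochastic matrices
for conservation, 500 small randomized cases against the sort-and-tally
oracle, 20 four-treatment scenarios at 100,000 draws for SUCRA/P-score
concordance, and 200 replicates per cell at 1000 draws for recovery —
chosen to keep Monte-Carlo error well below the asserted tolerances.

## Limitations

- Certainty of evidence is outside the metrics: a beading plot ranks, it
  does not grade. Rankings from sparse or inconsistent networks can be
  precise-looking and wrong.
- The estimates-to-draws bridge ignores covariance unless the data came
  versus a common reference with independent arms; for strongly
  correlated league tables, supply draws instead.
- Ranking metrics compress away the full rank distribution; the companion
  charts exist precisely so users can look underneath the single number.
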