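---
title: "Methods: measuring post-WGD fractionation with analytical units"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: measuring post-WGD fractionation with analytical units}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wgdfrac)
```

## Scope and model

After a whole-genome duplication (WGD) every gene starts with a paralog at
a positionally homologous location on a homeologous chromosome copy.
Collapse proceeds by *reduction* of duplicate pairs to single copy and by
chromosomal rearrangement. `wgdfrac` quantifies two aspects of this
process from a gene order plus a WGD paralogy map:

* whether the *pairs* chosen for reduction are scattered randomly
  (geometry of single-copy run lengths), and
* whether, within each reduced pair, the *surviving copy* falls on either
  chromosome with equal probability (concentration statistics).

All positions are 0-based gene-order ranks. Base-pair coordinates,
genome-halving distance computation, and BLAST itself are out of scope:
the halving distance `d` is always an input, and protein hit tables are
consumed pre-computed.

## Analytical units

The unit of analysis is the AU: two runs of single-copy genes bounded at
both ends by duplicate pairs. Formally, an adjacency `(p1, q1)` of
consecutive pillars (genes that still have their partner) on one
chromosome forms an AU with the adjacency of their partners when
`p2 = partner(p1)` and `q2 = partner(q1)` are themselves consecutive
pillars, in one of two orientations:

* **parallel** — the partner segment reads `p2 .. q2`,
  `strand(p1) = strand(p2)` and `strand(q1) = strand(q2)`;
* **inverted** — the partner segment reads `q2 .. p2`,
  with both bounding pairs on opposite strands.

Everything strictly between consecutive pillars is unpaired by
construction, so interior genes are single-copy; their strands are ignored
(only the bounding pairs carry the orientation evidence). The bounding
partners are forced, so an adjacency belongs to at most one AU, two AUs
may share a pillar but never interior genes, and the degenerate case of a
segment paired with itself is rejected. Both sides on one chromosome are
allowed. These requirements make it unlikely that rearrangement has
exchanged material across the unit boundary, which is what licenses
reading the interior as fractionation of originally duplicated positions.

`s` is the total single-copy content of an AU (both sides), `q` the
minority-side count. Because rearrangement scrambles which side descends
from which homeolog, sides are treated symmetrically and `q` runs only to
`floor(s/2)`.

## Geometric model of AU sizes

Under random, independent choice of pair to reduce, `N(s)` decays
geometrically. We fit

$$M(s) = N_1\,(1-p)^{s-1}, \qquad s \ge 1$$

by minimizing Pearson's chi-square over `(N1, p)`. The observed `N(0)` is
excluded by design: the model is extrapolated to
`N0_hat = N1/(1-p)` and compared with the observed count, so that an
excess of fully retained adjacent pairs (reduction-resistant regions)
appears as `N(0) > N0_hat` rather than being absorbed into the fit. The
extrapolation formula is our reading of "continue the fitted curve one
step down"; it is the unique value consistent with the fitted decay ratio
`M(s+1)/M(s) = 1 - p`.

Numerical choices:

* `p` is scanned on the grid `0.001, 0.002, ..., 0.999`; at each `p` the
  scale is profiled in closed form, `N1 = sqrt(sum(O^2/g) / sum(g))` with
  `g_s = (1-p)^(s-1)` (the exact stationary point of the chi-square in
  `N1`). The best grid point is then refined locally with
  `stats::optimize` (tolerance 1e-8).
* Sparse tail bins are pooled from the largest `s` downward until every
  pooled expected count reaches `min_expected` (default 1; set 5 for the
  textbook-conservative rule). Pooling uses the profiled `N1` at the
  candidate `p`, then re-profiles on the pooled bins.
* Degenerate histograms (fewer than three distinct sizes `s >= 1` with
  positive counts) are rejected with an error rather than fitted.

Scale equivariance holds by construction: doubling all counts doubles
`N1` and leaves `p` unchanged (up to pooling-boundary effects, which the
tests avoid by using histograms whose expected counts stay above the
pooling floor).

## Concentration statistics

If each reduced pair keeps either copy independently with probability
1/2, the minority count of an AU of size `s >= 2` follows the folded
binomial

$$P(s,q) = b(s,q) + b(s,s-q) \ \ (q < s/2), \qquad
  P(s,s/2) = b(s,s/2) \ \text{(even } s\text{)},$$

with `b` the Binomial(s, 1/2) mass; counting the midpoint once makes the
cumulative `B(s, floor(s/2))` exactly 1. AUs with `s = 1` carry no
information (only one fractionation is possible) and `s = 0` none at all;
both are excluded from concentration statistics but kept in histograms
and fits.

The empirical counterpart `Fhat(s,q)` is compared against simulated null
genomes matched in `(n, m, d)`. For every size `s` present in the real
genome, every `q` in `0..floor(s/2)`, and every replicate containing at
least one AU of size `s`, the point
`(x, y) = (replicate Fhat, real Fhat)` is classified above/on/below the
diagonal. Two conventions matter here:

* **Full q grid.** Points are emitted for the whole `q` grid of each
  size, not only the cells the real genome happens to occupy.
  Conditioning on real occupancy of the exact cell `(s, q)` inflates the
  real cumulative systematically (we measured an off-diagonal
  above-proportion near 0.67 for *null* genomes under that convention,
  versus 0.5 under the full grid); the full grid keeps real and simulated
  genomes exchangeable under the null, which the control tests require.
* **Exact comparison.** Above/on/below is decided on cross-multiplied
  integer counts (`a*B` vs `b*A`), never floating-point equality, so
  "on the diagonal" means exactly equal fractions.

Per-size proportions are reported both over all points and with
on-diagonal points excluded; many cells tie exactly (both cumulative
fractions 0 or 1), so the off-diagonal version is the informative bias
measure and the one centred at 0.5 under the null. Multi-descendant WGDs
are summarized by an unweighted mean across descendants at sizes present
in all of them.

## The collapse simulator

`simulate_descendant()` is both the matched null generator and the
package's synthetic-data generator. It emulates:

* a doubled ancestor of `num_pairs` pairs on `num_chromosomes` pre-WGD
  chromosomes (near-even multinomial allocation, minimum one gene each),
  each chromosome duplicated, strands random but equal within a pair;
* reduction of exactly `m` pairs by deletion runs: drawn length
  `L ~ Geometric(1/mu)` on support `>= 1` (so `mu = 1` is single-gene
  deletion), uniform random start among copies of unreduced pairs, run
  walks rightward and truncates at the chromosome end, at an
  already-single gene (a pair never loses both copies), or at the `m`
  quota; the event log records drawn and realized lengths;
* per-run retention bias: survivors sit on chromosome copy A with
  probability `retention_bias` (0.5 = null);
* `d` rearrangements: inversions (reverse order, flip strands) and
  reciprocal translocations (exchange tails) at `inversion_fraction`
  (default 0.5); a translocation with fewer than two non-empty
  chromosomes falls back to an inversion, flagged in the log.

The interleaving of deletions and rearrangements is not biologically
constrained by anything we model, so it is a policy: the default
scatters the `d` rearrangements uniformly along the deletion timeline
(thresholds drawn on `0..m`); `deletions_first` and
`rearrangements_first` are available. All randomness flows through R's
seeded RNG; identical config and seed give identical event sequences, and
replaying the event log from the ancestor reproduces the output genome
exactly.

What the generator does **not** emulate: unassembled short contigs (the
contig filter exists for real data, defaults 2 duplicated or 10
single-copy genes), gene family expansion and tandem duplication,
missing or mis-assigned paralogies, variation in gene density, and any
selection structure beyond the single retention-bias parameter. Passing
the simulation-based tests therefore shows the statistics behave
correctly under the stated stochastic model, not that real genomes obey
that model.

## Problem sizes used by the tests

The test suite runs the simulation experiments at sizes chosen to give
stable statistics in minutes on one core:

* *Null control*: `num_pairs = 3000, m = 2727, d = 136` — the
  deletion-run experiment's ratios (`m/num_pairs = 10/11`,
  `d = 500/11000` of the ancestor pairs) at ~27% scale. Twenty null
  pseudo-real genomes are pooled against one 200-replicate ensemble, the
  pooled-control design (a single genome's off-diagonal above-proportion
  has sd ≈ 0.06 under the null; pooling twenty brings the band check to
  sd ≈ 0.013).
* *Bias and deletion-run direction*: retention bias 0.8 against a
  50-replicate ensemble at the control size; `mu = 2` versus `mu = 1` at
  `num_pairs = 5500, m = 5000, d = 250` (half the full experiment, the
  largest size at which 20 seeded repetitions stay within a few minutes),
  with 10-replicate ensembles per seed.
* The full-size deletion-run experiment
  (`num_pairs = 11000, m = 10000, d = 500`, 200 replicates) is available
  as `run_deletion_length_experiment()` defaults. Note these are the only
  self-consistent full-scale conditions: with `n` the present-day gene
  total and `m` the single-copy count, the ancestor holds
  `(n + m)/2 = 11000` pairs, of which `m = 10000` are reduced.

## Known limitations

* `m` for real data counts *all* unpaired genes after filtering;
  never-duplicated genes cannot be separated from reduced pairs without
  outgroup curation (`verify_singletons()` supports that step when hit
  tables exist).
* The contig filter counts pair membership once, against the unfiltered
  map; it is not iterated after partners are lost with their contigs.
* Best-reciprocal-hit ties are broken lexicographically (warned); genes
  with no lower-outgroup hit pass the bracket's lower bound vacuously and
  genes with no upper-outgroup hit fail its upper bound, both
  configurable.
* AUs are not chained into larger consolidated regions, and no attempt is
  made to assign AU sides to ancestral homeologs — rearrangement makes
  that assignment unrecoverable in general.
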