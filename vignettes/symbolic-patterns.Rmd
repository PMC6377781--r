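---
title: "Symbolic pattern analysis of time-series expression profiles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Symbolic pattern analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(funheatmap)
```

## The model

`funheatmap` treats a gene's time course not as a curve to be fitted but
as a word over a three-letter alphabet. For each time point `t` the pair
(log2 fold change, p-value) is mapped to a symbol:

* `+` when `log2FC(t) >= tau` and the significance gate passes,
* `-` when `log2FC(t) <= -tau` under the same gate,
* `0` otherwise,

and the symbols are concatenated into a *pattern key* (`"++-"` = up, up,
down). Genes are then grouped by exact key equality. This is a
deliberately assumption-free representation: no smoothness, no
autoregressive order, no monotonicity. Its power is that exact string
matching makes multi-dimensional questions — which patterns dominate,
which genes synchronize across cohorts, which genes respond early or
late — cheap set operations instead of model comparisons.

The price is that a key says nothing about shape *within* the
significant band: fold changes (2, 3, 4) and (5, 4, 3) both read `+++`.
The *trend key* recovers shape by encoding the sign of the change
between adjacent time points on the log2 scale. Two alphabets are
supported:

* `diff_only`: `T - 1` symbols, one per adjacent pair; the natural
  reading of "values are increasing";
* `baseline_inclusive` (default): a leading symbol for the change from
  baseline (log2 FC 0) to the first time point, then the `T - 1`
  differences — one symbol per time point, which is what per-time-point
  trend displays need.

Both are exposed because both readings are legitimate; exports always
label the mode. `trend_key(c(5,4,3) in linear scale)` is `"+--"`
baseline-inclusive and `"--"` diff-only.

### Statistical assumptions

The package consumes *precomputed* differential-expression statistics
(fold changes and p-values from limma, DESeq2, EDGE, t-tests, ...). It
therefore inherits, and does not re-examine, the upstream model's
assumptions. The discretization itself assumes only that the per-time-point
statistics are comparable across genes within a cohort, and that
up/down/neutral at the chosen thresholds is a biologically meaningful
trichotomy.

## Tunable parameters

| parameter | default | units / domain | rationale |
|---|---|---|---|
| `fc_threshold` | 1.0 | log2 fold change | linear 2-fold, the conventional DEG cutoff |
| `p_threshold` | 0.05 | probability; `NULL` disables | conventional significance gate; FC-only mode for inputs without p-values |
| `p_direction` | `"less"` | `less`/`greater` | significance normally means `p < alpha`; the inverted gate is kept selectable for auditing inputs whose columns encode 1 − p |
| trend `mode` | `baseline_inclusive` | — | one symbol per time point; `diff_only` matches the verbal "increasing/decreasing" reading |
| `zero_band` | 0 | log2 fold change | exact sign by default; raise to absorb numerical noise in near-flat profiles |
| `max_size` / `min_size` | 1000 / 3 | genes | "super large" pathways bias enrichment; "thousands of genes" is bounded at 1000, and sets under 3 genes are untestable |
| `merge_cut` | 0.15 | distance in [0, 1] | merges pairs with ≥ 85% overlap rate (see below) |
| enrichment `universe` | `measured` | — | the defensible null: genes that could have appeared in the query |
| `correction` | `BH` | — | conventional for enrichment lists; `none` reproduces a plain hypergeometric report |

Threshold comparisons are inclusive (`>=`, `<=`) on both sides.

## Design choices that were genuinely open

**Fold-change scale.** Input tables conventionally carry *signed linear*
fold changes (−2 means halved expression), while thresholds and plots
live on the log2 scale. The canonical internal scale is log2: signed
linear `v` maps to `log2(v)` for `v >= 1` and `-log2(-v)` for
`v <= -1`; 0 maps to 0; values strictly inside (−1, 1) are rejected as
ambiguous rather than silently interpreted. One canonical scale keeps
every downstream rule (discretization, trends, consolidation means,
line charts) unambiguous.

**Overlap distance and the merge cut.** The overlap rate
`min(|A|,|B|) / |A ∪ B|` is a similarity in (0, 1] that equals 1 iff
the sets are identical — note it is not Jaccard: disjoint equal-size
sets score 0.5, because the numerator is the smaller set's size, not
the intersection. A similarity cannot serve directly as a clustering
distance, so the package clusters `d = 1 − overlap` with average
linkage and cuts the tree at height 0.15, which corresponds to an 85%
overlap rate; the cut is a user parameter. Average linkage comes from
`stats::hclust`; merge heights under average linkage are monotone, so
cutting the full tree equals stopping agglomeration at the first merge
above the cut — the property the test suite exploits by comparing
against an exhaustive O(n³) agglomerator on small random databases.
Exact distance ties (duplicate pathways) are merged in library order;
all orders give the same flat clusters below the cut, and the output is
re-sorted by smallest member id so results are deterministic.

**Significance gate direction.** The gate is implemented as
`p < p_threshold`. Descriptions of DEG filters occasionally print the
inequality the other way; because silent guessing is worse than a
visible switch, the direction is a rule parameter (`p_direction`)
defaulting to the conventional reading.

**Pooled entries versus unique genes.** The combined view pools
*(cohort, gene)* entries, so a gene measured in three cohorts counts
three times in a pooled pattern group — that is what per-cohort
sub-pattern membership counts need. The strict per-gene question
("identical key in every cohort") is a different operation,
`synchronized_genes()`, rather than a hybrid of the two semantics.

**Region matching.** A Venn region ("significant at time points 1, 2
and 5") is by default *exact*: the named positions must match their
symbol constraints and every other position must be `0`, which is what
a single region of a Venn diagram means. An `at_least` mode relaxes the
other positions. Matches are stratified by the sub-key restricted to
the query positions; the strata partition the match set, e.g. the
2³ = 8 up/down combinations at three positions.

**Consolidation.** Cohorts with different time grids are aligned by
averaging log2 fold changes within user-specified, order-preserving
groups of time points. Means are only defined for the values; for
p-values the conservative maximum is the default, with Fisher's
combination as an option — combining dependent per-time-point p-values
is approximate either way, and the maximum never overstates
significance.

**Null group.** The all-`0` key is usually the overwhelming majority
and carries no pattern information, so it is dropped from group lists
by default — but its size is always reported, preserving the partition
identity `sum(group counts) + null count = number of profiles`.

**Sort order.** Group sorts are stable, by descending count with ties
broken by key under the fixed collation `'+' < '-' < '0'`. The
collation is arbitrary but fixed; determinism of exports matters more
than any particular order.

**Enrichment universe.** `measured` (default) intersects the measured
genes with the database's gene universe; `db_union` serves when no
cohort is loaded; `custom` accepts an explicit background. The choice
and resulting `N` are recorded in every result. Identifier matching is
case-insensitive exact string matching — no alias resolution, which
users must harmonize upstream. Pathways with zero overlap are reported
as untested rather than given p = 1 rows.

## Numerical choices and degenerate inputs

* The hypergeometric upper tail is `phyper(k − 1, K, N − K, n,
  lower.tail = FALSE)`, which works in log space; `k = 0` returns
  exactly 1. The suite verifies it against direct summation of
  `exp(lchoose(...))` terms over every instance with `N <= 30`.
* `trend_key` uses `|Δ| <= zero_band` (inclusive) so `zero_band = 0`
  means exact sign; a constant profile maps to all `0`.
* Rows with unparseable numeric cells are rejected with a row-level
  report (`rows_in = rows_parsed + rows_rejected` always holds); blank
  fold-change cells reject the row unless `allow_missing` imputes a
  neutral symbol and flags the profile.
* A consolidation that collapses the whole grid produces a valid
  one-time-point table; pattern and trend operations require `T >= 2`
  and say so.
* Exports format floats at 10 significant digits and order keys
  deterministically, so byte-identical reruns are a tested contract.
* The provenance line in every export carries an FNV-1a hash of the
  analysis parameters (output paths excluded), so files from different
  runs of the same analysis are comparable.

## The synthetic-data generators

`generate_cohort()` plants pattern groups directly: requested keys get
the requested gene counts, significant positions sit at
±(`fc_magnitude` = 1.5 log2 units, i.e. ≈ 2.8-fold) plus a uniform
jitter of up to 0.25, neutral positions are drawn uniformly from the
middle half of the neutral band (±0.5 × threshold), and p-values land
in [1e−5, 0.01] at significant positions and [0.2, 0.9] elsewhere.
Because the pipeline consumes precomputed DEG statistics, controlling
the discretized outcome is all a fixture needs; the generator does
*not* emulate count noise, gene–gene correlation, heteroskedastic
variance, or borderline fold changes that straddle the threshold.
Passing recovery tests therefore shows the machinery is exact on its
own terms — planted structure in, identical structure out — not that
the thresholds are well-calibrated for any particular real assay.
Specs that would cross the threshold (effect below the cutoff, noise
band reaching it) are rejected as infeasible rather than generated.

`generate_gmt()` inverts the overlap-rate formula to plant pairs with a
target overlap: for sizes `s_i, s_j` the required intersection is
`m = s_i + s_j − min(s_i, s_j)/rate`, rounded and checked to within
0.02 of the target. Unplanned pathways get disjoint gene sets, whose
mutual overlap rate is at most 0.5 and which therefore never merge at
any cut below 0.5.

## Problem sizes in the test suite

The suite runs cohorts of 3–25 genes over 2–5 time points, 1000 random
set pairs for the overlap oracle, 200 random databases of up to 8
pathways for the clustering oracle (exhaustive agglomeration is O(n³),
so small n is where it is trustworthy *and* fast), every hypergeometric
instance with `N <= 30`, and 50 seeds for planted-structure recovery.
These sizes make each oracle exhaustive or near-exhaustive at its scale
while the whole suite stays fast; the operations themselves are
vectorized string/set manipulations whose cost grows linearly in genes
and quadratically in pathways (the overlap matrix), so behaviour at
realistic scale (10⁴ genes, 10³ pathways) is the same code on bigger
inputs.

## Known limitations

* No richer alphabets (magnitude levels, slope symbols) — the
  three-level alphabet is the design point; extending it would touch
  only `discretize()`.
* No curve fitting or autoregressive/spline trend models; the symbolic
  trend is exactly the sign of differences.
* No gene-identifier namespace translation across cohorts or into the
  pathway database.
* Enrichment is over-representation only (no ranked GSEA, no GO-graph
  correction).
* The merge step is quadratic in the number of pathways; databases of
  ~10⁴ sets will want pre-filtering.
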