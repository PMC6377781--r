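# funheatmap

Symbolic pattern recognition for time-series differential-expression
profiles.

## The problem

Time-series omics experiments ask three recurring questions: which
temporal patterns do most analytes follow, which analytes follow an
identical pattern across several cohorts (tissues, doses, strains), and
how do the biological functions behind those patterns evolve over time.
Conventional clustering heatmaps ignore time ordering, while parametric
trajectory models (autoregressive fits, splines) impose shape assumptions
that blur distinct sub-patterns.

`funheatmap` takes the symbolic-representation route instead. Each gene's
per-time-point statistics are discretized into a three-letter alphabet:

```
symbol(t) = '+'  if log2 FC(t) >=  tau   (and p(t) < alpha, when p-values are present)
            '-'  if log2 FC(t) <= -tau   (same gate)
            '0'  otherwise
```

with defaults tau = 1 (a linear 2-fold change) and alpha = 0.05. The
symbols are concatenated into a **pattern key** such as `++-` ("up, up,
down"), and genes sharing a key form a pattern group. Each group is
further split into **trend** sub-groups by the sign of the change between
adjacent time points (optionally including the change from baseline), so
that a rising profile with fold changes 2, 3, 4 and a falling one with
5, 4, 3 — both `+++` — are kept apart.

Around this core the package provides:

* multi-cohort pooling with synchronized-gene queries and Venn-style
  region stratification, plus time-grid consolidation by means;
* pathway-database deduplication: pairwise overlap rate
  `min(|A|,|B|) / |A ∪ B|`, average-linkage clustering of
  `1 − overlap`, and merging of clusters below a cut height
  (default 0.15, i.e. roughly 85% overlap);
* one-sided hypergeometric enrichment of any selected gene group, with
  Benjamini–Hochberg adjustment by default;
* seeded generators for cohorts with planted patterns and GMT databases
  with controlled overlap, so every step is testable offline;
* tab-delimited/JSON exporters and a CLI
  (`inst/cli/funheatmap`) with subcommands `patterns`, `trends`,
  `combine`, `merge-db`, `enrich`, `simulate`, `render`.

Inputs are precomputed DEG statistics (one tab-delimited table per
cohort: ID, optional Entrez/Symbol, per-time-point fold change and
optional p-value) and any pathway database in GMT format.

## Worked example

```r
library(funheatmap)

f <- system.file("extdata", "example_cohort.tsv", package = "funheatmap")
tab <- read_cohort_table(f)
tab
#> Cohort 'example_cohort': 5 genes x 3 time points (T1, T2, T3); p-values present

groups <- sort_groups(group_by_pattern(tab, disc_rule()), "count_desc")
groups
#> 3 pattern group(s) over 3 time points; null ('000') count: 1
#>   key count
#> 1 +++     2
#> 2 +0-     1
#> 3 ---     1
```

Two genes are at least 2-fold up at every time point; one (Gapdh-like)
never leaves the neutral band and lands in the reported null group. The
`+++` group hides two different shapes, which the trend decomposition
separates:

```r
group_by_trend(get_group(groups, "+++"), tab, mode = "diff_only")
#> Trends of pattern '+++' (diff_only mode): 2 sub-group(s), 2 genes
#>   trend count
#> 1    ++     1
#> 2    --     1
```

Merging the demo pathway database collapses its two near-identical
inflammation sets (overlap rate 10/11 = 0.91, distance 0.09 < 0.15)
while the housekeeping set stays alone:

```r
db <- read_gmt(system.file("extdata", "example_pathways.gmt",
                           package = "funheatmap"))
merged <- cluster_and_merge(db, cut = 0.15)
attr(merged, "report")
#>      merged_id                    member_ids n_members n_genes
#> 1 MRG_9143bcb6                  HOUSEKEEPING         1       4
#> 2 MRG_f0d91374 INFLAMMATION_A;INFLAMMATION_B         2      11
```

and any group can be tested for enrichment against the merged database
(here the toy universe is the 5 measured genes, so nothing is
significant):

```r
q <- tab$symbol[match(groups$members[["+++"]]$gene_id, tab$gene_id)]
enrich(q, merged, universe = "measured", measured_genes = tab$symbol)
#>     pathway_id                            name members_hit k K n N   p   q
#> 1 MRG_9143bcb6                    HOUSEKEEPING        actb 1 2 2 5 0.7 0.9
#> 2 MRG_f0d91374 INFLAMMATION_A | INFLAMMATION_B         tnf 1 3 2 5 0.9 0.9
```

Column `k` is the overlap between query and pathway, `K` the pathway
size, `n` the query size and `N` the universe size; `p` is the one-sided
hypergeometric upper tail and `q` its BH adjustment.

The same pipeline scales to several cohorts through
`combine_cohorts()` / `run_combined()`, giving pooled pattern groups,
per-cohort trend membership, synchronized genes and a line-chart export.

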