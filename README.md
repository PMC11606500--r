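# tcrfirst

A TCR-first toolkit for paired single-cell gene-expression + T cell receptor
(TCR) sequencing data.

Multimodal single-cell experiments on T cells deliver two layers per cell:
the transcriptome and the receptor. Conventional pipelines cluster on
expression and treat the TCR as an afterthought, which dilutes any signal
tied to a clone — a clone routinely spans several expression clusters, and
clone-level dynamics (e.g. a clonotype collapsing under treatment) are
invisible at cluster resolution. `tcrfirst` makes the receptor the primary
index: cells are grouped by clonotype, clonotypes by CDR3 similarity, and
the expression layer is interrogated per clone or per sequence cluster.

The package is for computational immunologists analysing 10x-style paired
GEx + VDJ data (including all four chains, alpha/beta and gamma/delta), and
for method developers who need a fully synthetic, ground-truthed test bed.

## What it computes

* **Repertoire construction** — reads `filtered_contig.csv` (or AIRR TSV)
  and Matrix Market count triplets, resolves each cell to at most one chain
  per group (highest UMI, deterministic ties), excludes multiplets and
  ambiguous dual-lineage cells, and keeps exactly the cells with both
  modalities.
* **CDR3 clustering** — all pairs of same-chain, same-length CDR3s at
  Hamming distance ≤ 1, found by wildcard hashing in linear time, clustered
  with the canonical Markov clustering (MCL) iteration (expansion 2,
  inflation 2); clusters are named by modal V/J genes and summarized by a
  position-frequency motif.
* **Neighbor enrichment** — a weighted CDR3 mismatch distance
  `d = 3·(Σ min(4, 4 − S_BLOSUM62) + 4·|ΔL|)` with neighbor radius 12.5; each
  clone's neighbor count among the `N` repertoire clones is tested against a
  50× shuffled-junction background (matched on V-gene, length and optionally
  pgen deciles) with the hypergeometric tail
  `P(X ≥ k), X ~ Hypergeom(N−1+M, K, N−1)`, Bonferroni-corrected.
* **Annotation** — receptor rules (MAIT = TRAV1-2 + TRAJ33/20/12,
  gamma-delta by chain presence, TRAV13-2×TRBV4-1 as CD1b/c candidate) plus a
  semi-supervised gating tree over capped-rank (UCell-style) signature
  scores.
* **Clonal dynamics** — frequency-normalized expansion, the paired selection
  filter (≥ 1% of either repertoire and ≥ 2-fold change), expansion bins,
  and rank-sum marker tables (|log2FC| ≥ 0.25, p < 0.05, top 30).
* **Toy V(D)J generative model** — synthetic paired repertoires with planted
  sequence clusters and treatment responders, exact and Monte-Carlo
  generation probabilities, and geometric-mean pgen banding.

## Worked example

```r
library(tcrfirst)
library(dplyr)

rep <- simulate_repertoire(500, seed = 7, planted_sizes = c(8, 10))
items <- cluster_chain_split(rep)$B

clusters <- cluster_cdr3(items)
glance(clusters)
#> # A tibble: 1 × 4
#>   n_clusters n_clustered_items n_singletons largest
#>        <int>             <int>        <int>   <int>
#> 1         41               122          396      10

bg  <- shuffle_background(items, fold = 50, seed = 8)
enr <- enrich_clones(items, bg)
glance(enr)
#> # A tibble: 1 × 6
#>   n_clones n_background radius alpha n_significant frac_significant
#>      <int>        <int>  <dbl> <dbl>         <int>            <dbl>
#> 1      518        25900   12.5  0.05            18           0.0347

tidy(enr) |> filter(significant) |> arrange(p_adj) |>
  select(v_gene, j_gene, cdr3_aa, k_rep, k_bg, p_adj) |> head(3)
#> # A tibble: 3 × 6
#>   v_gene  j_gene  cdr3_aa       k_rep  k_bg        p_adj
#>   <chr>   <chr>   <chr>         <int> <int>        <dbl>
#> 1 TRBV4-1 TRBJ2-5 CASSYYGDRTQYF     9    11 0.0000000282
#> 2 TRBV4-1 TRBJ2-5 CASSYYQDRTQYF     9    18 0.000000697
#> 3 TRBV4-1 TRBJ2-5 CASSYYPDRTQYF     9    19 0.00000101
```

Reading the numbers: 518 unique beta clones yield a 25,900-sequence matched
background; 41 Hamming-1 communities exist but only 18 clones (3.5%) carry
significantly more sequence neighbors than recombination chance predicts —
and the top hits are exactly the members of the planted 10-member cluster,
each seeing its 9 co-members (`k_rep = 9`) against a thin background
neighborhood (`k_bg`). `autoplot(enr)` draws the neighbor-count versus
adjusted-p overview; `plot_cluster_motif(clusters, id)` draws a cluster's
residue-frequency motif.

See the methods vignette (`vignettes/tcr-first-methods.Rmd`) for the models,
parameter meanings, and the design decisions behind the defaults.

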