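# dielsc

Analysis toolkit for diel (end-of-day vs end-of-night) droplet
single-cell RNA-seq of plant tissues — the kind of experiment that
profiles *Arabidopsis* root and shoot protoplasts at both ends of a
12 h/12 h photoperiod and asks which cell types change with the time of
day, how stable the inferred cell clusters are, and which individual
transcripts are di-cistronic (one RNA molecule spanning two annotated
genes, most notably mRNA–tRNA read-through isoforms with a tRNA-like
sequence, "TLS", implicated in graft mobility).

It is written for computational biologists who have tagged read
alignments (cell barcode + UMI) or cell × gene UMI matrices and want the
bespoke statistics of such studies as tested, composable R functions:
everything takes and returns tibbles (or a light `umi_counts` container
with `tidy()`/`glance()` methods), chains with the pipe, and plots via
`autoplot()`.

## What it computes

* **Quantification & QC** — `collapse_umis()` assigns reads to genes by
  strand-aware block overlap and counts distinct (cell, UMI) molecules;
  multi-gene reads are routed to the di-cistronic caller, not counted as
  expression. `filter_cells()` retains cells with ≥ 500 transcripts,
  ≥ 200 detected genes and ≤ 20% plastid-derived UMIs (all
  configurable).
* **Clustering & robustness** — `cluster_cells()` (normalize → PCA → SNN
  graph → Louvain, with a pluggable batch-correction hook) and
  `robustness_score()`: counts are binomially thinned to 80% in each of
  100 replicates, re-clustered with the original variable genes, and each
  original cluster *C* scored with its mean best-match co-occurrence

  `score(C) = 100 · mean_r max_C' |C ∩ C'| / |C|`,

  starred `[75,100] → ***`, `[50,75) → **`, `[25,50) → *`.
* **Markers** — `find_markers()`: one-vs-rest two-sided Wilcoxon on
  log-normalized expression with the thresholds fold change ≥ 0.25
  (natural log), expressing fraction ≥ 5%, Bonferroni-adjusted p < 0.05.
  `jaccard_overlap()` compares marker sets across clusterings with
  `J = |A∩B| / |A∪B|`; `time_composition()` and
  `split_markers_by_time()` analyse ED/EN structure;
  `hypergeom_enrichment()` tests functional categories with the
  upper-tail hypergeometric `P(X ≥ k)`, `X ~ HG(N, K, n)`.
* **Di-cistronic transcripts** — `detect_dicistronic_pairs()` calls gene
  pairs supported by ≥ 100 reads whose blocks overlap both genes, then
  keeps pairs that are protein-coding/same-strand or involve a non-coding
  gene. `classify_molecules()` labels host-gene molecules `tls` (≥ 1 read
  overlapping the tRNA) or `mono` (no tRNA contact, reads stopping before
  the tRNA start); `tls_cluster_enrichment()` reports per-cluster TLS
  ratios and the marker-rule enrichment verdict.
* **Synthetic data with planted truth** — `simulate_annotation()`,
  `sim_truth()`, `simulate_reads()`, `simulate_counts()` generate GFF3
  annotations, tagged reads and NB count matrices with planted clusters,
  markers, batch shifts, low-depth/high-plastid cells, junction-read
  support and per-cluster TLS fractions, so every stage is testable
  without external sequencing data. I/O covers GFF3, MTX + TSVs, and a
  documented tagged-read TSV dialect.

## Worked example

Simulate a two-cell-type experiment with 7 low-depth and 3 high-plastid
cells planted, then run the pipeline:

```r
library(dielsc)
library(dplyr)

truth <- sim_truth(n_cells_per_cluster = c(80, 80), n_low_depth = 7,
                   n_high_plastid = 3, seed = 11)
m <- simulate_counts(truth)
flt <- filter_cells(m)
flt
#> <umi_counts> 150 cells x 400 genes, 285798 UMIs total
#>   cell_meta: cluster, timepoint, replicate, low_depth, high_plastid, depth
```

Exactly the 10 planted bad cells were removed. Cluster, and score cluster
robustness under 100 rounds of 80% read subsampling:

```r
cl <- cluster_cells(flt, seed = 11)
rb <- robustness_score(cl, flt, n_replicates = 100, fraction = 0.8, seed = 12)
rb
#> # A tibble: 2 x 3
#>   cluster score stars
#>     <int> <dbl> <chr>
#> 1       1  96.2 ***
#> 2       2 100   ***
```

Both clusters keep ≥ 96% of their cells together across subsampled
re-clusterings — three-star robustness. Markers at the stated thresholds
recover the planted marker genes (10 per cluster, named `G0001`–`G0020`):

```r
find_markers(flt, cl) |> filter(is_marker) |> slice_min(p_adj, n = 3, by = cluster)
#> # A tibble: 6 x 8
#>   gene  cluster log_fc pct_in pct_out        p    p_adj is_marker
#>   <chr>   <int>  <dbl>  <dbl>   <dbl>    <dbl>    <dbl> <lgl>
#> 1 G0013       1   2.27      1   0.764 1.08e-23 4.31e-21 TRUE
#> 2 G0011       1   1.88      1   0.833 8.56e-22 3.42e-19 TRUE
#> 3 G0014       1   2.12      1   0.806 1.26e-21 5.04e-19 TRUE
#> 4 G0006       2   2.16      1   0.795 8.08e-23 3.23e-20 TRUE
#> 5 G0002       2   1.93      1   0.897 1.79e-22 7.16e-20 TRUE
#> 6 G0004       2   1.94      1   0.846 2.79e-22 1.12e-19 TRUE
```

Quantify mono- vs read-through isoforms of a host gene with a downstream
tRNA, with per-cluster read-through fractions planted at 10%, 3% and 2%:

```r
ann <- simulate_annotation(1, tls_host = TRUE, seed = 21)
tr2 <- sim_truth(n_cells_per_cluster = c(250, 250, 250),
                 tls_fractions = c(0.10, 0.03, 0.02), seed = 21)
reads <- simulate_reads(ann, tr2, depth_per_cell = 20)
mols <- classify_molecules(reads, "host01", "trna01", ann)
tls_cluster_enrichment(mols, truth_clusters(tr2), collapse_umis(reads, ann))
#> # A tibble: 3 x 8
#>   cluster n_cells n_tls n_mono tls_ratio    p_tls  p_mono enriched
#>     <int>   <int> <int>  <int>     <dbl>    <dbl>   <dbl> <lgl>
#> 1       1     238    68    670    0.0921 1.07e-10 0.00166 TRUE
#> 2       2     233    24    758    0.0307 2.34e- 2 0.0234  FALSE
#> 3       3     237    15    732    0.0201 2.59e- 5 0.373   FALSE
```

The estimated ratios (9.2%, 3.1%, 2.0%) recover the planted fractions,
and only the high-TLS cluster is called enriched: its TLS pseudo-gene is
a marker (p < 0.05, elevated) while mono is not; in cluster 3 the TLS
signal is significantly *depleted*, which correctly does not count.

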