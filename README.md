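# retfid

Cell-identity scoring and fidelity benchmarking of retinal organoid
scRNA-seq data.

## The problem

Retinal organoids derived from pluripotent stem cells are widely used to
model the developing and mature human retina, but differentiation protocols
vary in how faithfully the cells they produce recapitulate their in vivo
counterparts. `retfid` is for computational biologists who want to quantify
that fidelity from single-cell RNA-seq data: it builds cell-identity
references from fetal and mature retinal tissue atlases and scores organoid
datasets against them with six interpretable metrics.

## The core statistic

Everything rests on a rank-based **differential-stability score** per gene
and cell type, computed independently within each `(dataset, batch)`.
For each cell type *k*, genes are assigned ascending fractional ranks
(ties averaged, divided by the gene count *G*) on two stability statistics
over that type's cells:

- *r₁*: the fraction of cells with nonzero expression,
- *r₂*: the negated coefficient of variation (population SD / mean of the
  log-normalized values, zeros included; silent genes get CV = ∞).

The identity score of gene *g* in type *k* among *K* types is

```
s(g,k) = 1/(K-1) · Σ_{k'≠k} [ (r₁(g,k) − r₁(g,k')) + (r₂(g,k) − r₂(g,k')) ] / 2
```

Scores lie in (−1, 1) and sum to zero across types for each gene; a high
score marks a gene that is broadly and stably expressed in that type but
not in the others — a cell-identity gene. Because the statistic is
rank-based within each batch, it is robust to batch effects, which the
package quantifies directly (batch subsampling, principal variance
component analysis, clustering concordance).

On top of the scores the package provides:

- **References**: batch-averaged score matrices, pooled cell-type
  proportions, expression centroids, and age-ordered score profiles for
  mature, fetal, and early/late-fetal tissue groups.
- **Annotation confidence**: ensemble reclassification
  (nearest-centroid in PCA space) to keep only confidently labeled cells
  (probability > 0.9).
- **Maturation genes**: per-type Pearson correlation of identity scores
  with developmental age (days post-conception, min-max scaled), BH-adjusted
  within type (highly significant < 0.01, significant 0.01–0.05).
- **Markers**: top-scoring genes per type, novelty annotation from a
  literature query-count table, and validation via expression specificity,
  kNN classification (Pearson distance) and random-forest importance.
- **The six-metric benchmark**: cell identity vs the mature and the fetal
  reference (mean per-type Pearson r), maturation (signed correlation along
  age-ordered profiles; positive = adult-like), cell-type coverage,
  cell-type proportion (1 − total-variation distance), and the off-target
  cell fraction from nearest-centroid classification with rejection
  (`unassigned`/`intermediate`). Identity, coverage and proportion are
  min-max scaled across compared units; the combined score averages all six
  (oriented so higher is better) and ranks the units.
- **A simulator**: negative-binomial counts with log-normal gene
  abundances, planted markers, batch effects, age ramps, library-size
  variation, and organoid degradation knobs (identity noise, dropped types,
  proportion skew, off-target cells, age position) with full ground truth.

## Worked example

```r
library(retfid)

# a small synthetic tissue atlas: 4 batches, 7 cell types, planted markers
cfg <- sim_config(n_genes = 500, n_markers = 20, n_batches = 4,
                  cells_per_batch = 700, seed = 42)
tissue <- simulate_tissue(cfg)

batches <- lapply(split(seq_len(nrow(tissue$annotation)),
                        tissue$annotation$batch), function(i) {
  ids <- tissue$annotation$cell_id[i]
  list(matrix = expression_matrix(tissue$matrix$values[, ids],
                                  genes = tissue$matrix$genes, cells = ids,
                                  layer = "counts"),
       annotation = tissue$annotation[i, ])
})
ref <- build_reference(batches, group = "mature")
ref
#> <reference_atlas> group=mature: 500 genes x 7 types, 4 batches

markers <- select_markers(ref, top_n = 20)
head(markers$rod$gene, 5)
#> [1] "gene0339" "gene0362" "gene0132" "gene0314" "gene0190"

# two organoid units: one faithful, one degraded
good <- simulate_organoid(tissue$truth, organoid_sim_config(
  n_cells = 2000, protocol = "good", seed = 1))
poor <- simulate_organoid(tissue$truth, organoid_sim_config(
  identity_noise_sd = 0.6, dropped_types = "RGC",
  offtarget_fraction = 0.15, n_cells = 2000, protocol = "poor",
  batch = "org02", seed = 2))

report <- benchmark(list(
  list(protocol = "good", matrix = good$matrix, annotation = good$annotation),
  list(protocol = "poor", matrix = poor$matrix, annotation = poor$annotation)),
  refs = list(mature = ref))
report
#> <fidelity_report>
#>  protocol batch ci_mature ci_fetal maturation coverage proportion offtarget
#>      good org01     0.911       NA         NA    1.000      0.999      0.00
#>      poor org02     0.718       NA         NA    0.857      0.850      0.15
#>  combined rank
#>     1.000    1
#>     0.212    2
```

The faithful unit correlates with the reference identity profiles at
r = 0.91, covers all 7 expected retinal types, matches the tissue
proportions (0.999) and produces no off-target cells; the degraded unit
loses identity correlation, misses RGCs (coverage 6/7 = 0.857) and carries
its planted 15% off-target fraction. The `maturation` and `ci_fetal`
columns are `NA` here because no age-resolved (fetal) reference was
supplied. `write_report()` saves the tables as CSV plus a JSON archive.

A thin command-line wrapper is installed under
`system.file("cli", "retfid.R", package = "retfid")` with `ingest`,
`simulate`, `score` and `benchmark` subcommands.

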