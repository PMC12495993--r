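# panelcraft

Multi-view characterization and genetic-algorithm design of targeted gene
panels.

Targeted spatial transcriptomics platforms (Xenium, CosMx, MERFISH and
relatives) measure a fixed panel of typically 100–500 genes, so the panel
decides what a study can see. Most design tools optimize cell-type
classification alone. `panelcraft` instead scores a candidate panel against a
reference single-cell (optionally spatial) dataset across **five metric
categories**, and couples those metrics to an elitist genetic algorithm that
assembles panels directly:

| category | metrics |
|---|---|
| feature specificity | gene specificity scores (gsc), panel entropy, variation recovery (NMI), random-forest balanced accuracy |
| feature diversity | signed proportion of orthogonal vs redundant gene pairs under a Spearman threshold |
| biological inference | hypergeometric pathway over-representation with BH correction, Jaccard-pruned pathway diversity, ligand/receptor composition |
| spatial information | per-gene Moran's I on a k-NN graph, nearest-neighbor expression correlation |
| forward compatibility | perturbation-impact score behind a pluggable perturbation-model contract |

Core definitions, for gene g, cell type t, detection proportions
`p_in`/`p_out` (fraction of cells with a nonzero count in / outside type t):

- `gsc(g, t) = log2((p_in + ε) / (p_out + ε))`, ε = 0.01 — positive means
  specific for t.
- panel entropy `= 0.5·(1 − (I_grid + 1)/2) + 0.5·p₀`, where `I_grid` is
  Moran's I of the hierarchically clustered gsc heatmap under rook adjacency
  and `p₀` is the proportion of genes with no positive gsc; lower is better.
- feature diversity `D = (n_orthogonal − n_redundant)/n_pairs` with a pair
  redundant iff `|ρ_Spearman| ≥ τ` (τ = 0.3).
- Moran's I `= (N/W)·Σᵢⱼ wᵢⱼ(xᵢ−x̄)(xⱼ−x̄) / Σᵢ(xᵢ−x̄)²` on a row-standardized
  k-NN graph (k = 6).
- variation recovery `NMI = 2·I(U;V)/(H(U)+H(V))` between annotated cell
  types and a seeded k-means clustering on the panel-gene principal
  components.
- perturbation score of g `= Σ_{j≠g} |Δⱼ|·1[|Δⱼ| ≥ δ]`, rank-normalized over
  all genes a perturbation model covers.

Category scores live in [0, 1] and combine into a weighted overall score;
the optimizer (an elitist GA: population 50, panel size 200, up to 5000
iterations by default) maximizes an equally weighted mean of the
five cheap constituents (diversity, pathway diversity, 1 − entropy, spatial
score, NMI).

A seeded negative-binomial simulator (`simulate_dataset()`) generates
datasets with cell-type markers, a correlated housekeeping block, independent
noise genes and spatially clustered cell types, plus matching pathway and
ligand/receptor annotations — so the whole pipeline is testable offline.

## Worked example

```r
library(panelcraft)

cfg <- sim_config(seed = 7)                  # 3 types x 100 cells, 225 genes
ds  <- simulate_dataset(cfg)
ds  <- normalize_counts(filter_dataset(ds, filter_thresholds(1, 1, 1)))

mk  <- simulated_panel(ds, "marker")         # the 15 ground-truth markers
db  <- simulate_pathway_db(cfg)
lr  <- simulate_lr_table(cfg)

rep <- characterize_panel(ds, mk, db = db, lr_table = lr,
                          config = score_config(seed = 7))
glance(rep)
#> # A tibble: 1 × 6
#>   panel  specificity diversity biology spatial overall
#>   <chr>        <dbl>     <dbl>   <dbl>   <dbl>   <dbl>
#> 1 marker       0.815     0.857   0.711   0.609   0.748

head(tidy(rep), 3)
#> # A tibble: 3 × 6
#>   gene  specificity diversity biology spatial importance
#>   <chr>       <dbl>     <dbl>   <dbl>   <dbl>      <dbl>
#> 1 M1_1        1        0.357        0   0.616      0.493
#> 2 M1_2        0        1            0   0.123      0.281
#> 3 M1_3        0.682    0            1   0.651      0.583
```

The category scores say the marker panel separates cell types well
(specificity 0.82: high balanced accuracy, low panel entropy, high NMI), is
largely non-redundant (diversity 0.86 on the (D+1)/2 scale), recovers its
cell-type pathways (biology 0.71) and is spatially informative (0.61, i.e.
mean Moran's I ≈ 0.22). Per-gene importance min–max-normalizes each gene's
contribution within the panel and averages across categories.

Panel optimization and the disk-level workflow:

```r
ga <- ga_config(candidate_pool = ds$gene_ids, panel_size = 20,
                population = 30, max_iters = 200, seed = 7)
st <- optimize_panel(ga, ds = ds, db = db)   # elitist GA, memoized objective
st$best_objective; autoplot(st)              # non-decreasing trajectory

run_simulate(cfg, "fixture/")                # writes MTX + labels + coords +
run_characterize(ds, list(mk), "out/", db = db, lr_table = lr)  # GMT + LR CSV
```

A thin CLI wrapping `run_simulate` / `run_characterize` / `run_optimize` is
in `inst/cli/panelcraft.R`.

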