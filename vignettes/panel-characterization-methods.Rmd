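---
title: "Methods: multi-view gene-panel characterization and optimization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-view gene-panel characterization and optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelcraft)
```

# The problem

A targeted spatial transcriptomics experiment assays only the genes on its
panel. Whether a panel is "good" depends on the study: classifying cell types,
covering pathways of interest, avoiding redundant probes, retaining spatial
signal, or staying informative under future perturbation experiments.
`panelcraft` quantifies all five views against a reference dataset — a
cells × genes count matrix with cell-type labels and, optionally, planar
coordinates — and feeds the same metrics into a genetic algorithm that builds
panels.

This vignette documents the models, the tunable parameters, the numerical
conventions, and the design decisions that were genuinely open, in that
order. It states no empirical result that the package's tests and acceptance
script do not themselves compute.

# Preprocessing

Quality filters run in a fixed order — genes with total counts below 10,
then cells with totals below 200, then cell types left with fewer than 10
cells — with totals recomputed after each step. Thresholds are strict
("less than"): items exactly at a threshold are kept. Filtering is
idempotent.

Published panel-scoring workflows rarely state their normalization, so the
package uses the single-cell convention: counts-per-10⁴ followed by
natural `log1p`,

$$\mathrm{lognorm}_{ig} = \ln\!\left(1 + 10^4 \frac{c_{ig}}{\sum_g c_{ig}}\right).$$

All correlation- and clustering-based metrics (feature diversity, variation
recovery, classification, spatial metrics) read this layer; detection-rate
metrics (gsc) read raw counts, where a zero is a zero regardless of depth.

# Feature specificity

**Gene specificity score.** For gene $g$ and cell type $t$, with detection
proportions $p_{in}$ (fraction of cells of type $t$ with a nonzero count) and
$p_{out}$ (same over all other cells),

$$\mathrm{gsc}(g,t) = \log_2 \frac{p_{in} + \varepsilon}{p_{out} + \varepsilon},
\qquad \varepsilon = 0.01 .$$

Detection proportion, rather than mean expression, is used because targeted
platforms are most sensitive to whether a transcript is seen at all, and
because it makes the score robust to library-size variation. The pseudocount
bounds the score (at most $\log_2(1.01/0.01) \approx 6.66$) and keeps it
finite for all-zero genes.

**Panel entropy.** The gsc matrix is hierarchically clustered on rows and
columns (average linkage, Euclidean distance; leaf order as produced by
`stats::hclust`, whose tie-breaks are deterministic in the input order), then
treated as a grid of units with binary rook (4-neighbor) adjacency, over
which Moran's I, $I_{grid}$, is computed. With $p_0$ the proportion of
low-specificity genes — genes whose gsc is non-positive for *every* cell
type — the score is

$$E = \tfrac12\left(1 - \tfrac{I_{grid}+1}{2}\right) + \tfrac12 p_0 \in [0,1],$$

lower is better. The two terms are an equally weighted convex combination so
that the score stays informative when either term degenerates. $p_0$ is
deliberately a per-gene quantity: a perfect marker panel in a $T$-type
dataset has $(T-1)/T$ of its matrix *entries* non-positive by construction,
so an entry-level proportion would penalize exactly the panels the score is
meant to reward; the per-gene reading counts only genes that are specific to
nothing. A zero-variance gsc matrix gets $I_{grid} = 0$ and a degenerate
flag, so a constant positive matrix scores $0.25$ by the formula.

**Variation recovery.** Cells are clustered by k-means ($k$ = number of
annotated types unless overridden, 10 restarts, seeded) on the top
$\min(20, n_{genes}-1)$ principal components of the panel-gene lognorm
submatrix, and compared with the annotation by normalized mutual information
with arithmetic-mean normalization, $\mathrm{NMI} = 2 I(U;V)/(H(U)+H(V))$.
The annotation labels are the reference partition — deterministic and
directly interpretable — rather than a full-transcriptome clustering, which
would add a second stochastic stage; NMI estimates from very small panels
are noisy and should be read with caution. When both partitions are trivial
(zero entropy on both sides) the NMI is defined as 1.

**Classification.** A random forest (`ranger`, 500 trees, default feature
subsampling) under stratified 5-fold cross-validation, seeded. Balanced
accuracy is the unweighted mean of per-class recall pooled over folds, so
rare cell types count as much as abundant ones; per-fold balanced accuracies
are kept for standard errors. Any classifier with a fit/predict contract
could be substituted; no hyperparameter tuning is attempted.

# Feature diversity

Pairwise Spearman correlations over cells on lognorm for all panel-gene
pairs; a pair is redundant iff $|\rho| \ge \tau$ ($\tau = 0.3$, exposed in
`score_config()`), and

$$D = \frac{n_{orthogonal} - n_{redundant}}{n_{pairs}} \in [-1, 1].$$

The signed form is used because a plain proportion cannot go negative, while
fully redundant panels should be clearly flagged ($D = -1$ when every gene is
duplicated). Rank-based correlation makes $D$ invariant to strictly monotone
per-gene transforms. Zero-variance genes have no defined rank correlation;
their pairs are assigned $\rho = 0$ with a warning rather than dropped, so
the pair count stays interpretable.

# Biological inference

Over-representation per pathway is the one-sided hypergeometric tail
(equivalently one-sided Fisher) on the overlap between panel and pathway,
both intersected with the universe, followed by Benjamini–Hochberg
correction across all tested pathways; significance is $q < \alpha$
($\alpha = 0.05$). The universe defaults to all genes of the filtered
reference dataset — the set a panel was actually drawn from — and is
exposed in the API. Percent enriched genes uses the panel∩universe size as
denominator; both counts are reported.

Pathway diversity prunes near-duplicate significant pathways greedily:
visit by ascending $q$ (ties: larger overlap, then name), keep a pathway iff
its Jaccard similarity with every kept pathway is $\le 0.7$. The score is
kept/total, defined as 1 when at most one pathway is significant. Jaccard is
computed on full member sets (intersected with the universe), not only on
panel genes, which is stabler for small panels.

Ligand/receptor composition is a flat classification against an annotation
table; a gene listed as both ligand and receptor is category "both" and
counts once in the LR proportion.

# Spatial information

The spatial graph is k-nearest-neighbor by Euclidean distance ($k = 6$, the
hexagonal-packing convention for tissue), distance ties broken by lower cell
index, weights row-standardized by default. Per gene, Moran's I

$$I = \frac{N}{W}\,\frac{\sum_{ij} w_{ij}(x_i-\bar x)(x_j-\bar x)}{\sum_i (x_i-\bar x)^2}$$

is computed on lognorm (sparse matrix algebra; the test suite checks it
against an $O(n^2)$ double loop and `ape::Moran.I`). Zero-variance genes are
flagged degenerate and score 0. Nearest-neighbor correlation is the Pearson
correlation between each cell's expression and the mean over its $k$
neighbors — "nearest neighbors" is read as the k-NN set, not the single
nearest cell. The panel-level spatial score is the mean over non-degenerate
genes of $(I+1)/2$.

# Forward compatibility

Perturbation impact is scored behind a model contract: anything exposing
`covered_genes` and `respond(gene)` (a named vector of log-fold-change-like
effects) qualifies — a precomputed response-matrix CSV from any simulator
plugs in unchanged. The per-gene score combines "number and magnitude" of
influenced genes as a thresholded L1 mass,
$s(g) = \sum_{j \ne g} |\Delta_j|\,1[|\Delta_j| \ge \delta]$ with
$\delta = 0.1$; panel scores are means of scores rank-normalized to $[0,1]$
against all covered genes (ties take mid-ranks), which makes panels
comparable across models with different effect scales. Panel genes outside a
model's coverage are excluded and reported as coverage. The bundled
`linear_response_model()` is a seeded sparse random effect matrix with
optional dense "hub" rows, sufficient to exercise every property of the
contract.

# Aggregation

Category scores, each in $[0,1]$: specificity = mean(balanced accuracy,
$1-E$, NMI); diversity = $(D+1)/2$; biology = mean(% enriched genes, pathway
diversity, LR proportion); spatial = mean $(I+1)/2$; forward = panel
perturbation score. Categories whose optional inputs (pathway database,
coordinates, perturbation model) are absent are dropped and the non-negative
category weights renormalized, making the overall score invariant to
positive rescaling of all weights. Per-gene importance min–max-normalizes
raw per-gene sub-scores *within the panel* (a gene's contribution to this
panel, not a global quantity); a degenerate range (e.g. a single-gene panel)
yields 0.5 with a warning.

The optimizer objective is deliberately cheaper than the overall score: an
equally weighted (overridable) mean of $(D+1)/2$, pathway diversity, $1-E$,
the spatial score, and NMI. The classifier and the perturbation model are
excluded — cross-validated forests per candidate panel would dominate the
runtime of every GA generation, and the five retained constituents already
span four categories. The overall score and the objective are therefore
distinct, documented quantities.

# The genetic algorithm

Defaults: 50 random duplicate-free panels of 200 genes, up to 5000
iterations. Each iteration scores the population (memoized on sorted panel
content — the cache changes runtime, never results), keeps the top 20%
unchanged (elitism, which guarantees a non-decreasing best trajectory), and
refills by mutating uniformly chosen elites: 5% of panel genes (at least
one) are replaced by uniform draws from the unused candidate pool.
Single-point set-crossover between two elites is available behind
`crossover_prob` (default 0, mutation-only), since published descriptions of
replacement-based panel GAs do not require it. Convergence is declared when
the best score has not improved by more than `tol` ($10^{-6}$) for
`patience` (200) consecutive iterations. Runs are fully deterministic given
the config seed. Any function mapping a gene vector to $[0,1]$ can be
injected as the objective.

# The synthetic generator

`simulate_dataset()` draws negative-binomial counts (dispersion 0.5) with:
per-type marker genes (mean $4\times$ the baseline of 1 count in their own
type), a housekeeping block sharing one log-normal latent factor per cell —
the minimal mechanism producing the correlated, type-independent expression
that makes stably-expressed-gene panels score as redundant — independent
noise genes, log-normal library-size multipliers (CV 0.3), and cell types
scattered (SD 1) around distinct blob centers on a circle of radius 5, so
marker expression is spatially clustered. Gene names encode ground truth
(`M{t}_{i}`, `HK_{i}`, `NZ_{i}`), letting tests select panels without
bookkeeping.

Defaults are 3 types × 100 cells, 5 markers per type, 10 housekeeping and
200 noise genes. The noise background is sized so the gene universe is an
order of magnitude larger than a panel: over-representation analysis only
has power when a pathway-sized overlap is improbable by chance, which a
universe of a few dozen genes cannot provide. Companion generators emit a
pathway database aligned to the markers (one program per type, a
housekeeping set, random extras) and a ligand/receptor table; their RNG
streams are offset from the dataset seed so that independently drawn
artifacts (panels, pathways, annotations) never share draws.

What the generator does *not* emulate: ambient RNA, doublets, batch effects,
realistic tissue morphology, gene-length or GC biases, or empirical marker
hierarchies. Passing tests therefore demonstrate correctness of the metrics
and the documented qualitative behaviors (marker panels beat noise panels on
specificity metrics, housekeeping blocks flag as redundant, spatially
organized expression scores high Moran's I) — not performance claims on any
real tissue.

# Numerical choices and degenerate inputs

- Zero-variance inputs: Moran's I returns 0 with a degenerate flag (both for
  genes and for the entropy grid); diversity assigns $\rho = 0$ to pairs with
  a constant gene; NN correlation reports NA.
- k-NN distance ties break by lower cell index; duplicate coordinates are
  allowed.
- Greedy pathway pruning breaks $q$ ties by larger overlap, then pathway
  name; hierarchical-clustering leaf order follows `stats::hclust`.
- Rank normalization of perturbation scores uses average ranks mapped to
  $[0,1]$ by $(r-1)/(n-1)$; a single covered gene maps to 1.
- Every stochastic step (k-means restarts, fold assignment, forests, GA,
  simulator) is seeded from an explicit integer; identical seeds give
  byte-identical files.
- Test and acceptance problem sizes: 300 cells × 225 genes for the fixture;
  $n = 50$ units for Moran oracle checks; universes ≤ 500 for enrichment;
  a 12-gene pool with $\binom{12}{3} = 220$ enumerable panels for the GA
  optimum check. These sizes were chosen as the smallest at which each
  property is non-trivial.

# Known limitations

- The gsc uses detection proportions; on deeply sequenced data where most
  genes are detected everywhere, contrasts compress and the entropy score
  loses resolution.
- NMI for very small panels (a handful of genes) fluctuates with k-means
  initialization despite seeding across datasets.
- The enrichment model is ORA, not ranked GSEA; pathway topology is ignored.
- Moran's I is computed at the cell level; sub-cellular binning is out of
  scope.
- The GA is a single-population elitist design; island models and
  reinforcement-learning variants are not implemented.
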