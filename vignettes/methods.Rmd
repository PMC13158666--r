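---
title: "Models and procedures behind spatialprox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and procedures behind spatialprox}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`spatialprox` analyzes targeted in-situ spatial transcriptomics at
single-molecule resolution: each observation is an RNA molecule with a 3D
position (pre-expansion micrometres), a gene label, a cell assignment, an
optional nuclear/cytoplasmic compartment, and a field-of-view (FOV) tile.
This vignette explains the statistical models, the parameters that matter,
the synthetic data the package validates itself on, and the choices made
where the design was genuinely open.

## Distances and proximity

The package distinguishes two distance conventions. On platforms that
resolve individual molecules well (expansion sequencing, STARmap,
synthetic tissues) the distance between two cells is the **cell-boundary
distance**: the minimum 3D Euclidean distance over all pairs of their RNA
molecules. On centroid-convention platforms (MERFISH, Xenium) distances are
between cell centroids and nearest-neighbor searches are capped at 145 µm,
the diagonal of a 100 µm FOV — beyond the cap a neighbor is treated as
absent. All thresholds are inclusive: a cell at exactly 1 µm is proximal.

Boundary distances are exact but naively quadratic in molecule count; the
implementation prunes candidate target cells with the bound
`boundary(a,b) ≥ ‖centroid(a) − centroid(b)‖ − r(a) − r(b)` (r = the cell's
maximal molecule-to-centroid radius) and evaluates candidates in
lower-bound order, stopping once the bound passes the current minimum. The
result is identical to the exhaustive minimum (tested against it).

Scoping: the distance-response analysis restricts nearest-neighbor
searches to the query cell's FOV on boundary-convention platforms (tiles
are the unit in which distances are trustworthy there); all other modules
search the whole tissue. Cells whose molecules straddle a tile border
belong to the FOV holding the majority of their molecules. Cells with
fewer than 50 detected transcripts are dropped at ingest (configurable).

## Shared permutation machinery

Almost every test in the package follows one recipe: compute an observed
statistic, recompute it under many random relabelings, fit a normal
distribution to the permuted values, and report the tail probability of
the observed value under that fit (the *normal-approximation permutation
procedure*). The normal fit lets the tests report p-values far below the
1/(B+1) resolution of a purely empirical null; its adequacy is checked by
the calibration suite (below). Degenerate nulls (zero permutation
variance) return p = 0.5 at the mean and 0/1 beyond it, with a warning.
Benjamini–Hochberg adjustment (`q`) is applied within the family each
module defines; `stats::p.adjust` is the single implementation and is
tested against the step-up definition directly.

## Proximity-associated dispersion

For a cell-type pair (i, ii) in one tissue, type-i cells are split into
proximal (boundary distance ≤ 1 µm to any type-ii cell) and distant. The
type-i count matrix is z-scored per gene and embedded by PCA; statistics
live in PC1–PC2. Two statistics are computed: the sum of distances from
proximal cells to the overall type-i centroid (dispersion) and the
distance between the proximal and distant centroids (separation). Labels
are shuffled preserving the proximal count; each statistic is z-scored
against its own permutation distribution and combined as
`z_max = max(z_single, z_two)` — the max acknowledges the two measures are
correlated. The observed `z_max` is then referred to the permuted `z_max`
distribution (each permutation's pair of statistics z-scored against the
full permuted marginals and the max taken) — the null construction for the
max was unspecified in principle and this symmetric choice keeps the
observed and permuted quantities on the same scale. The proximity
contribution to variance is the ratio of proximal to total dispersion;
under exchangeability its expectation is the proximal fraction, which the
test suite verifies.

Pair eligibility requires at least one proximal, one distant and three
total type-i cells (the last is the engineering minimum for a 2-PC
embedding). A sensitivity mode drops the reference type's marker genes
before embedding, guarding against segmentation bleed-through.

## The negative-binomial DE engine

Counts from targeted panels are overdispersed; the engine models them as
NB with a log link. Size factors are median-of-ratios against a
geometric-mean pseudo-reference (falling back to positive-count geometric
means when no gene is detected everywhere, as is common in sparse panels).
Per-gene dispersions are method-of-moments estimates shrunk halfway (in
log space) toward a fitted `a + b/µ` trend; they depend only on the counts,
not the labels, so permutation reruns reuse them. Group log-means are
fitted by Newton iteration with size-factor exposures and compared by a
Wald test using observed Fisher information. Deliberate simplifications:
no Cook's-distance outlier handling and no independent filtering. The
engine is cross-checked in the test suite against an established NB DE
implementation on planted data — direction and magnitude of strong effects
agree, and evidence ranks correlate.

The permutation wrapper shuffles the two-group labels (1000 by default)
and reports per gene `(1 + #{|stat_perm| ≥ |stat_obs|})/(B + 1)` alongside
the nominal Wald p; both are BH-adjusted, and genes are flagged by an
absolute log2 fold-change filter (default 1, configurable — the filter
value was an open choice). Note the empirical permutation p is floored at
1/(B+1); with a 299-gene family that floor cannot reach q < 0.05 at
B = 1000, so headline significance calls rest on the (calibration-checked)
nominal q with the permutation p as a concordance diagnostic.

## Triplets, overlaps, bacteria

Triplet contrasts pool tissues and compare focal type-A cells proximal to
type B only against cells proximal to both B and C (≤ 1 µm each); a
contrast is valid with at least five cells per condition. Cross-tissue
overlap of significant gene sets is tested by resampling both sets from
the expressed background 100 000 times (the add-one-smoothed tail matches
the hypergeometric tail to Monte-Carlo accuracy).

Bacterial 16S molecules are DBSCAN-clustered per FOV in 3D
(`min_samples = 3`, the neighborhood count including the point itself —
held fixed). A cluster's compactness (sum of pairwise member distances) is
compared against size-matched random draws from the FOV's most abundant
host gene; significance is the lower tail (tighter than host RNA). The ε
grid is swept and the ε maximizing F1 (precision = significant/all
clusters, recall = clustered/all bacterial molecules) is selected, ties
toward the smallest ε. With uniform background noise present, recall —
and hence the F1 argmax — keeps growing with ε until merged clusters stop
being significantly compact, so the selected radius sits above the true
cluster scale; in noise-free configurations it lands within a small
multiple of it. Host cells are classified as *include* (≥ 1 significant
bacterial molecule inside), *proximal* (≤ 1 µm) or *distant*, and
include-vs-distant contrasts run through the shared DE engine.

## Spatial RNA velocity

Nuclear counts play the role of unspliced u, cytoplasmic counts of
spliced s. Cytoplasmic depth is normalized per cell (divide by the cell's
cytoplasmic total, multiply by the global mean total). Counts are smoothed
over each cell's K = 30 nearest neighbors in PC1–PC3 of the normalized
cytoplasmic matrix. The degradation rate γ per gene is the
origin-constrained least-squares slope of u on s over the cells in the
extreme 7.5% quantiles of total expression — the regression direction
follows the steady-state identity of the velocity model v = u − γs (a
textual description elsewhere reverses the roles of u and s; the equation
is authoritative, so u is regressed on s). Genes qualify as reliable when
their maximum depth-normalized compartment expression (scaled to [0, 1]
by the global maximum) reaches 0.038. Future states S(T) = S(0) + vT use
T = 3, are floored at zero, and are checked against a 10% bound on
per-cell total drift. PCA axes are fitted on the normalized *current*
states only and future states are projected into those fixed axes (fitting
on current states keeps the axes stable; joint fitting is a defensible
alternative and is isolated behind this one function). The magnitude of
change is the PC1–PC2 distance between the projections, the current
magnitude is the distance from the origin, and the phase is the
displacement angle in (−π, π]. Distance associations use Pearson
correlation with distance-shuffling permutation nulls; the phase uses a
circular–linear correlation with the same null, since an angle cannot be
Pearson-correlated directly.

## Distance- and neighbor-response regressions

Distance response: per tissue and ordered type pair, X cells with a valid
nearest-Y distance are collected (FOV-scoped for boundary platforms,
145 µm-capped centroids otherwise); genes are dropped when their 98th
expression percentile is ≤ 10 counts or they are detected in ≤ 20 cells;
raw counts are regressed on distance by OLS (raw counts keep the
count-based filters meaningful; normalized expression is a config option).
Each gene also gets the mean R² over 100 distance shuffles as a noise
floor. q-values are global across all gene × pair × tissue tests.
Significant hits must additionally survive a robustness filter: cells
sorted by distance, expression smoothed by a Gaussian kernel with σ = 5 in
rank units (σ is in sorted-order units because the smoothing operates on
the sorted vector), re-regressed, and kept only if the smoothed R² ≥ 0.5
(0.3 as the relaxed variant for centroid platforms). Reported records are
ranked by a composite score: eight features ranked best-to-worst
(|slope|, R², smoothed R², cell count, 98th percentiles of expression and
distance descending; mean permuted R² and q ascending), each rank reversed
to n − rank and summed, so scores span [0, 8(n − 1)].

Neighbor response: Y neighbors within 15 µm are counted per X cell
(10/20 µm as robustness cutoffs, 40 µm centroid-based for Xenium-style
data); neighbor-count bins with fewer than 10 cells are dropped and pairs
need ≥ 4 surviving bins; genes are reduced to the top 20% by variance. The
primary estimator resamples 10 cells per bin, fits OLS, and averages the
slopes of 1000 iterations, refitting the intercept to the original data
(ȳ − b·x̄). The per-gene p is the median of the per-iteration coefficient
p-values — how to combine 1000 iteration p-values was an open question;
the median is conservative and the standard all-cells OLS p is retained in
the output for audit. BH runs across the genes of each pair. Alternatives:
inverse-bin-frequency WLS (raw and sum-to-one-normalized weights are
provably identical), and line aggregation (evaluate all iteration lines on
the observed neighbor-count grid, pool, single OLS — the grid choice makes
the estimator well-defined). A consensus set intersects the significant
gene × pair sets across all methods and cutoffs and applies a 10%
reference-detection filter when matched single-cell data exist.

## Program concordance across tissues and platforms

Per cell-type pair, each tissue/platform profile contributes the −log10
p-values of its proximity contrast, restricted to genes expressed (total
count > 0 in the relevant cell type) in every profile. Exact zeros are
replaced by 0.8 × the global minimum nonzero p before the log. Columns are
z-scored across profiles and the matrix embedded by PCA with a
deterministic sign convention (each component's largest-magnitude loading
positive). Component significance shuffles each gene across profiles
10 000 times and compares explained-variance fractions. Paired
(ExSeq-vs-MERFISH-style) and group (shared receptor status) tests measure
mean PC1–PC2 distances; each permutation re-shuffles genes, re-embeds, and
affinely rescales each permuted axis's [min, max] onto the observed
axis's [min, max] (the anchor points of the rescaling were unstated; the
range map preserves relative positions while aligning scales), and the
p-value is the lower tail — closer than chance.

## Cell typing

Reference markers come from matched single-cell DE tables: genes with
average log2 fold change > 5 and adjusted p ≤ 1e-200 ("p ≈ 0"); a gene
marking several types is kept only for a type that uniquely reaches p ≈ 0,
otherwise dropped; canonical markers join by union. In-situ counts are
clustered over a grid of PCA depths (6–30) × Louvain resolutions
(0.2–2.0) on a kNN graph — the backend is deliberately generic (depth
normalization, log, per-gene scaling, PCA, modularity communities) and
pluggable. Cluster assignment uses one-vs-rest Wilcoxon overexpression
tests of the marker genes (rank-sum is robust for sparse panels; the
original cluster-level test was unspecified), BH-corrected, with the
q ≤ 1e-9 single/multi-marker rules and the log-ratio dominance rule
`log10(q1/q2) < 0.3·log10(q2)` for competing types. Consensus labels
require the modal assignment to appear in ≥ 20% of retained solutions
(those inferring > 3 types) and in ≥ 10 solutions. Validation shuffles
counts across cells within each gene — destroying co-expression while
preserving each gene's marginal — and compares the number of validly
labeled cells against that null.

## The synthetic-tissue generator

`simulate_tissue()` emulates the data the analysis stack consumes: cells
placed uniformly in a thin 300 × 300 × 10 µm slab (tiled into 100 µm
FOVs), five types with tumor-microenvironment-like proportions
(tumor 0.40, T 0.20, B 0.15, macrophage 0.15, endothelial 0.10), a
299-gene panel with a shared lognormal baseline summing to ~170
transcripts per cell and eight markers per type elevated 25-fold *on top*
of the baseline — elevation is not renormalized away, so marker-bearing
types simply carry more transcripts and the panel keeps well-expressed
non-marker genes, as a real targeted cancer panel does. NB dispersion is
0.3. Molecules scatter isotropically around the cell center (σ = 4 µm
cytoplasmic, half that nuclear and axially), so cell "boundaries" emerge
from the molecule clouds and boundary distances flow through the same
code path as real data. Roughly: ~170+ transcripts/cell matches reported
per-cell read depths; a ~10 µm section with ~4 µm clouds produces contact
geometry in which a few tens of percent of cells have a ≤ 1 µm neighbor
of another type.

Planted effects modify NB means as functions of *measured* spatial
covariates (computed with the package's own distance machinery on the
realized tissue) and redraw only the targeted genes' counts, so ground
truth and measurement agree by construction: proximity shifts add Δ for
proximal cells; distance/neighbor effects set µ = max(0, a + b·x); triplet
effects multiply µ by a factor in condition-2 cells; bacteria shifts add Δ
in cells containing planted 16S molecules. Velocity planting treats
existing counts as cytoplasmic and draws nuclear counts u ~ Poisson(γs)
(inflated in induced cells); bacterial planting adds Gaussian 16S clusters
anchored on cell centroids plus uniform background noise.

What the generator does **not** emulate: tissue morphology and spatial
clustering of cell types, segmentation errors, platform-specific noise
(optical crowding, probe efficiency), and correlated gene programs beyond
the marker blocks. Passing tests therefore demonstrate that the
statistical machinery recovers what it claims under its own model
assumptions — not that those assumptions hold in any particular tissue.

## Validation sizes and reproducibility

The self-validation (test suite and `scripts/acceptance.R`) uses reduced
problem sizes chosen to exercise every code path at desk scale: null
calibration uses 60-cell two-type tissues with 400–500-shuffle nulls over
300–500 replicates per test family; γ recovery uses a 2000-cell tissue;
slope recovery uses 300-cell regressions over 20 replicates; the
end-to-end cohort uses two 350-cell tissues over the full 299-gene panel
with one planted effect per analysis module. Every stochastic step takes
an explicit integer seed, and the generator is byte-reproducible given
one.

## Known limitations

* The NB engine omits outlier refitting and independent filtering; with
  very small groups its Wald p-values lean anti-conservative, which the
  permutation p's flag.
* The median-of-iteration-p rule for the balanced-sampling regression
  bounds attainable significance by the per-iteration sample size
  (10 × the number of valid bins).
* Boundary distances assume molecules are assigned to the correct cell;
  segmentation bleed-through between touching cells mimics proximity
  effects (partially addressed by the marker-exclusion sensitivity mode).
* Phase–distance association uses a circular–linear correlation whose null
  is permutation-based; no parametric phase model is attempted.
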