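---
title: "Aligning paired single-cell datasets with coupled self-organizing maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aligning paired single-cell datasets with coupled self-organizing maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jsomap)
```

## The model

`jsomap` aligns two cell-by-feature datasets that observe related biology
through different feature panels. Its central assumption is that a subset of
features corresponds across the datasets — the *shared features* — and that
cells of the same type have similar profiles over them. Everything else may
differ: the private features, the measurement scale, the noise structure,
and even the set of populations present.

Two self-organizing maps share one rectangular grid of $m \times n$ nodes.
Node $j$ carries a codebook vector $V_j^{(1)}$ in dataset 1's feature space
and $V_j^{(2)}$ in dataset 2's. Before training, a *matching function* links
each cell to its most related cell in the other dataset using the shared
features only, together with a matching weight $\delta \in [0,1]$.
Training interleaves, per iteration and per drawn cell $X_i$:

* the classical SOM update at the cell's best-matching unit $b$ and its grid
  neighborhood $N_\varepsilon(b)$ on its *own* map:
  $V_j \leftarrow V_j + \delta_i\,\alpha\,(X_i - V_j)$ for
  $j \in N_\varepsilon(b)$;
* the *joint* update: at that same node set, the **other** map is moved
  toward $X_i$'s matched partner $\tilde X_i$ from the other dataset, again
  weighted by $\delta_i$.

Each map therefore learns its own dataset's topology (clustering power is
retained, including over private features), while the joint updates force
corresponding populations onto the same grid region (alignment). Because
$\delta \alpha \in [0,1]$, every update is a convex combination: codebook
components can never leave the range spanned by the data and the
initialization, which the test suite asserts as an invariant.

## Matching modes

**Correlation mode** (default): each cell of one dataset is matched to the
cell of the other dataset with the highest Pearson correlation over the
shared features, and $\delta$ is that correlation. Negative correlations are
clamped to 0: $\delta$ multiplies the learning rate, and a negative weight
would push codebooks *away* from data, destabilizing training. The literal
signed value can be retained with `allowNegativeDelta = TRUE` for
comparison. Cells that are constant across the shared features have
undefined correlation and receive $\delta = 0$ (they neither drive nor
distort the coupling) with a warning.

**Binary mode**: intended for cytometry panels, where gating logic is a
cascade of positive/negative marker calls. Each shared feature is binarized
at a two-segment step-fit threshold: values are sorted, every split into a
low and a high segment is scored by the summed squared error around the two
segment means, and the threshold is the midpoint of the means at the best
split (computed in $O(\mathrm{len})$ with prefix sums; ties go to the
smallest split). The similarity of two cells is the fraction of markers on
which their calls agree, and $\delta$ is that fraction. A feature constant
in either dataset carries no step and is dropped from both sides to keep
the positional correspondence.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `m`, `n` | 10, 10 | grid rows/columns; 100 nodes suits $10^3$–$10^4$ cells |
| `epochs` | 3 | passes over the larger dataset; each point is used at least three times |
| `alpha0` | 0.9 | initial learning rate, decays linearly |
| `alphaFinal` | 0.01 | learning rate at the last iteration |
| `epsilon0` | `ceiling(2(max(m,n)-1)/3)` | initial neighborhood radius in grid units (6 for 10×10) |
| `downsampleTarget` | 10000 | per-dataset training cap |
| `outlierPercentile` | 1 | density percentile treated as outliers before downsampling |

The radius default deserves a note: the intent is a radius that starts wide
— about a third of the grid diameter, so early updates organize the whole
map — and shrinks linearly until only the best-matching unit is updated
(any $\varepsilon < 1$ reaches only the BMU on an integer grid). An
alternative rule `2*max(m,n) - 13` is selectable via
`defaultEpsilon0(literal = TRUE)`; it coincides in spirit on large grids but
is negative below 7×7, so the diameter-based form is the default and
`epsilon0` can always be set directly. Both $\alpha$ and $\varepsilon$ decay
per iteration (not per epoch); the final iteration pins them exactly at
(`alphaFinal`, 0).

Where the independent updates are concerned, $\delta$ appears in the update
formula and is applied there by default (`deltaInIndependent = TRUE`);
setting it `FALSE` confines $\delta$ to the joint updates, since its purpose
— trusting a cross-dataset match in proportion to its strength — only
involves the coupling. With `joint = FALSE` and unit weights the procedure
reduces exactly, draw for draw, to two independent classical SOMs; the test
suite verifies bit-level equality against an independently written SOM.

## Sampling, downsampling and determinism

Cells are drawn by per-epoch random permutations (each point of the larger
dataset used exactly `epochs` times; the smaller dataset's permutations are
recycled); i.i.d. draws are available via `sampling = "iid"`. Datasets above
the cap are reduced by density-dependent downsampling: the local density of
a cell is the number of cells within a kernel radius (5 × the median
nearest-neighbor distance — the multiplier is configurable, as no canonical
constant exists), cells below the 1st density percentile are set aside as
outliers, and each remaining cell is kept with probability
$\min(1, \mathrm{TD}/\mathrm{density})$, where the target density TD is
found by bisection so the expected kept count meets the cap. Rare
populations thus survive nearly intact while abundant ones are thinned.
Matching is computed *after* downsampling, on exactly the rows used for
training; assignment afterwards always covers the full datasets. With
downsampling disabled, a dataset above the cap is reduced by plain uniform
sampling instead, since the cap itself is unconditional.

A single integer seed drives initialization (uniform draws within each
feature's observed range, $V^{(1)}$ then $V^{(2)}$), the sampling
permutations (dataset 1 then dataset 2), and the downsampling draws; the
update loop consumes no randomness. Runs are therefore bit-reproducible, and
the JSON map container round-trips codebooks at full double precision.

Deterministic tie-breaking is applied throughout: best-matching units and
argmax matches go to the lowest index, majority labels to the
lexicographically smallest label, and step-fit splits to the smallest split
point.

## Post-training analysis

* `assignToNodes()` assigns every cell to its nearest node on its own map.
* `superposeCluster()` concatenates each node's two codebooks and clusters
  nodes by Ward linkage on Euclidean distances (via `stats::hclust`,
  `ward.D2`), cut at `K = max(m, n)` by default.
* `modeMap()` / `compositionTable()` summarize per-node majorities and the
  distribution of each label across node clusters.
* `transferLabels()` labels query cells by their node's reference majority;
  a node empty in the reference borrows the nearest non-empty node's label
  (lowest index on ties) and flags the cell as imputed. This fallback is a
  totality device, not part of the core procedure.
* `scoreFit()` reports node purity, matching score, shared-feature RMSE and
  average KL divergence. In the purity and matching scores, nodes occupied
  by only one dataset contribute no cross-matches but their cells stay in
  the denominator; unlabeled cells are excluded with a warning. KL uses
  natural logarithms and an unweighted mean over non-empty groups.

## The synthetic generator

`generatePaired()` emulates the intended use case at desk scale: $k$
Gaussian clusters with centers separated by at least `clusterSep` noise SDs
in an 8-dimensional shared space, observed by two modalities that add their
own private features (whose cluster centers are drawn at the same scale, so
private features carry real cluster structure) and a per-feature affine
distortion $a x + b$, $a \sim 1 + N(0, \sigma_d)$, $b \sim N(0, \sigma_d)$,
on dataset 2's shared coordinates. Optionally one cluster is omitted from
dataset 2, emulating a population present in a single modality. The defaults
(5 clusters, 500 cells per cluster and dataset, separation 6, distortion
0.05) describe a clearly clustered, mildly distorted regime in which a
correct implementation should align nearly perfectly — the validation suite
requires matching and purity scores of at least 0.90 there, and checks that
matching quality degrades monotonically as the distortion grows through 0.3
and 1.0.

What the generator does *not* emulate: count noise (negative binomial,
dropout), library-size variation, doublets, nested or overlapping
populations, or feature spaces where the shared panel is uninformative.
Passing tests on this generator demonstrate correctness of the machinery,
not performance on any particular real dataset.

```{r example, eval = FALSE}
sim <- generatePaired(simSpec(seed = 11))
fit <- runJsom(sim$d1, sim$d2, sim$shared, jsomConfig(seed = 11))
scoreFit(fit, cellLabels(sim$d1), cellLabels(sim$d2), sim$shared)
```

## Preprocessing

For real inputs the package provides the conventional steps:
`arcsinhTransform()` (cofactor 150 for flow cytometry, 5 for mass
cytometry), `log1pTransform()` for scRNA-seq counts, `filterCells()`
(detected-gene bounds 200–2500 inclusive, mitochondrial fraction at most 5%,
prefix `MT-` configurable), `selectHVG()` by raw variance-to-mean dispersion
(population variance; features with mean 0 rank last), and `pcaReduce()`
(user-chosen component count — 20 and 30 are typical for PBMC-scale data;
no permutation analysis is performed to choose it automatically). The
matching features and the training features need not coincide: a common
practice is matching on overlapping highly variable genes while training on
per-dataset PCA coordinates.

## Problem sizes and numerical choices in the validation suite

The suite validates at sizes chosen to exercise every code path while
keeping a full run around a minute: pipelines of 2 × 2,500 cells on a 10×10
grid (3 epochs ≈ 7,500 iterations), the SOM-equivalence check at 2,000
cells, metric and step-threshold oracles at 200 and 500 random instances,
and the downsampling balance check at 10,000 cells. The acceptance script
reruns the 2 × 2,500-cell conditions end to end.

## Known limitations

* Exactly two datasets; extending the coupling to three or more maps would
  need a redesign of the matching bookkeeping.
* Alignment quality is bounded by the quality of the matching function: if
  the shared features cannot separate the populations, the coupling aligns
  noise. The mean $\delta$ reported by `runJsom(verbose = TRUE)` is the
  first diagnostic to inspect.
* The two datasets should contain mostly the same populations. A population
  private to one dataset is tolerated (it settles on nodes unoccupied by
  the other dataset, as the one-sided-cluster validation checks), but many
  disjoint populations with spuriously strong matches can corrupt the
  alignment.
* The shared-feature RMSE is only meaningful when the shared columns are on
  commensurate scales in the two training spaces.
* Grids are rectangular with Euclidean neighborhoods and a hard cutoff;
  hexagonal or toroidal topologies and Gaussian kernels are out of scope.
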