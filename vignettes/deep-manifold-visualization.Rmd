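---
title: "Deep manifold visualization: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep manifold visualization: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmviz)
```

## The problem and the model

Droplet-based single-cell RNA-seq yields a sparse nonnegative count matrix
(cells x genes) whose intrinsic dimensionality is far below the number of
genes. `dmviz` learns a parametric map from expression profiles to a 2- or
3-dimensional latent space — Euclidean for *static* data (discrete cell
types) or hyperbolic (Poincaré ball / Lorentz model) for *dynamic* data
(branching differentiation), where volume grows exponentially with radius
and trees embed with low distortion.

The encoder is a six-layer fully connected network split into two modules:

* a **structure module** `d' -> 500 -> 300 -> 100` that produces a
  100-dimensional *structure embedding* `z^st`, and
* a **visualization module** `100 -> 300 -> 100 -> p` (p = 2 or 3) whose raw
  output is mapped onto the chosen manifold by the exponential map at the
  origin.

Hidden layers use batch normalization and LeakyReLU; the final layer of each
module is linear. Because every manifold point is produced by `exp_o`,
ordinary Adam optimizes all weights — no Riemannian optimizer is needed.

Training compares two fully connected similarity graphs over each minibatch
and its mixup augmentations:

* the **structure graph** `u^st`: Euclidean distances between structure
  embeddings, with the distance between a cell and its own augmentation
  divided by a contraction coefficient `gamma` (so the kernel treats a cell
  and its interpolated neighbour copy as near-identical — a learned,
  sharpened notion of locality);
* the **visualization graph** `u^vi`: manifold distances between latent
  points, plus `beta * D_E(y_i, y_j)` added to the kernel argument, where
  `y` is the multi-hot batch encoding. Cross-batch pairs therefore need a
  *smaller* embedding distance to achieve the same similarity as same-batch
  pairs: the batch separation is absorbed by the prior batch graph instead
  of the layout. The encoder itself never sees `y` ("batch-invariant"), so
  a trained model maps new batches.

Distances are converted to similarities by the t-distribution kernel

    g(D | nu) = C_nu * (1 + D/nu)^-(nu + 1),
    C_nu = 2*pi * ( Gamma((nu+1)/2) / (sqrt(nu*pi) Gamma(nu/2)) )^2,

with `nu_st = 100` (near-Gaussian, sensitive over the data's own distance
scale) for the structure graph and a heavy-tailed `nu_vi` (default `5e-3`)
for the visualization graph, then symmetrized by the fuzzy union
`u_ij = u_i|j + u_j|i - 2 u_i|j u_j|i`. The training loss is a fuzzy
cross-entropy between the two graphs, summed over ordered pairs.

## The two loss forms, and why the default is the standard one

Two variants of the pair loss are implemented (`loss_form` in
`similarity_config()`):

* `standard_fuzzy_ce` (default):
  `s log(s/v) + (1-s) log((1-s)/(1-v))` with `s = u^st`, `v = u^vi`.
  It is nonnegative, zero iff the clamped graphs agree, and its gradient in
  `v` vanishes at `v = s` — attraction when the embedding underestimates a
  similarity, repulsion when it overestimates it.
* `as_printed`: `s log(s/v) + (1-v) log((1-v)/(1-s))`, which mixes the two
  memberships asymmetrically. Its derivative in `v` equals `-2` at `v = s`
  and stays negative over the attainable range, i.e. every pair attracts at
  every distance. In our experiments this collapses the embedding to a
  point (held-out cell-type accuracy at chance). It is kept selectable for
  sensitivity analysis, not used for training.

Both forms clamp similarities to `[eps, 1-eps]` (`eps = 1e-6`) before
logarithms; clamped entries receive zero gradient.

A related subtlety: the kernel's normalizer caps `u^vi` at
`C_{nu_vi} ≈ 0.008` while structure similarities of very close pairs
approach 1. Pairs whose target exceeds the cap saturate into pure
attraction; pairs with near-zero targets feel the `(1-s)/(1-v) ≈ 1`
repulsion. The balance of the two shapes the layout, much as in other
neighbour-embedding methods.

## Training the structure graph, and the initialization that makes it work

Both graphs are differentiable functions of the network and both receive
the loss gradient (a `detach_structure` switch can freeze the structure
side; in our experiments joint training recovers geometry markedly better,
e.g. the depth-radius correlation on the trajectory benchmark rises from
near zero to ~0.75, so joint training is the default).

The t-kernel at `nu_st = 100` is scale-sensitive: `g(D) ≈ e^{-D}` for
moderate `D`. A randomly initialized deep network compresses all pairwise
distances into a narrow band around ~1, where *every* pair looks similar
and the loss degenerates. `dv_train()` therefore calibrates the
initialization once: after building the network it rescales the structure
module's final linear layer so the median pairwise distance of the initial
structure embedding equals the median pairwise distance of the input (on a
subsample of up to 512 cells). The structure graph then grades
neighbourhoods over the data's own distance range from the first step;
training refines it from there. The visualization module's last layer is
scaled by 0.1 at initialization so hyperbolic runs start near the disk
centre, clear of the `acosh` saturation region.

## Preprocessing and reference mapping

`fit_preprocess()` learns, in the order applied: library-size normalization
to `target_sum` (default `1e4`), `log1p`, per-gene standardization (zero
standard deviations recorded as 1), and PCA with `min(50, n-1, d)`
components. Every statistic is frozen; `apply_preprocess()` reuses training
means, deviations and loadings verbatim. A raw-gene mode (`use_pca =
FALSE`) feeds the `d` genes to the encoder directly.

Heterogeneous queries go through `align_genes()` first: shared genes keep
their values, genes missing from the query are zero-filled, extra genes are
dropped, and zero overlap is an error rather than a silent all-zero
mapping. `predict()` on a fitted model is exactly
`align_genes -> apply_preprocess -> forward pass` with batch-norm layers in
evaluation mode — nothing refits, so new datasets land in the training
latent space.

## Hyperparameters

| parameter | default | role |
|---|---|---|
| `nu_st` | 100 | structure-kernel tail; near-Gaussian |
| `nu_vi` | 5e-3 | visualization-kernel tail (typical range 1e-3..1e-2) |
| `gamma` | 1000 | cell-augmentation scale contraction (range 10..1e5) |
| `beta` | 1 | batch-graph weight (range 1e-2..100); 0 disables |
| `p_u` | 1 | upper end of the mixup ratio `r ~ U(0, p_u)` |
| `k_neighbors` | 10 | input k-NN graph for augmentation |
| `learning_rate` | 1e-3 | Adam step (typical grid {1e-3, 5e-3}) |
| `batch_size` | 1000 | minibatch of original cells (grid {500, 1000, 2000}) |
| `epochs` | 300 | full passes; 50-100 suffice at desk scale |
| `K` | 1 | curvature magnitude of the hyperbolic space |

The depth-radius correlation on the trajectory benchmark keeps its sign
across `gamma` in {10, 1000, 1e5} and `nu_vi` in {1e-3, 5e-3, 1e-2}; the
defaults sit at the grid midpoints. At the benchmark sizes used here
(600-1200 cells) we train with `batch_size = 500`, which gives several
optimizer steps per epoch and noticeably better geometry than a single
full-batch step; the package default stays at 1000, the middle of the
typical range, suited to datasets of tens of thousands of cells.

## The synthetic-data generator

Real accession-scale datasets are out of scope, so every end-to-end claim
is exercised on a generator that emulates the statistical regime the method
targets. Cells live on a 10-dimensional latent manifold and are lifted into
gene space by a seeded random orthonormal map with gain 2.5 on top of
per-gene base log-means `N(log 20, 0.5)`; counts are negative binomial
(size 2) on the exponentiated log-means with an independent dropout mass
(`sparsity`, default 0.3 — the realized zero fraction tracks it within a
few points; droplet data is often far sparser, which the `sparsity`
parameter can emulate).

* `make_clusters()` places cluster centres on a centred simplex with
  pairwise latent distance `separation` (default 10) against unit
  within-cluster noise. The defaults were calibrated once so that distinct
  "cell types" are nearly perfectly separable in the preprocessed input
  (5-NN accuracy ~1.0), as real major cell types are: a generator whose
  *input* is not separable cannot probe whether the *embedding* preserves
  separability.
* `make_tree_trajectory()` grows a rooted tree whose root is itself a
  branch point: `branching_factor` arms leave the origin in independent
  random directions, and each level splits every branch again, directions
  perturbing the parent's. This makes the root the hub of the tree — as a
  zygote-like progenitor is — which is precisely the property behind
  "root cells near the centre of the Poincaré disk": hyperbolic layouts
  centre the hub. (An earlier single-trunk design made the first branch
  point the hub, and the embedding — correctly — centred that instead.)
  Branch segments span 6 latent units, calibrated once so the *input*
  depth signal (Spearman of true depth vs distance-from-root in PC space)
  is ~0.85, representative of a well-resolved developmental dataset.
* `inject_batch_effects()` overlays crossed categorical factors; each level
  shifts its cells' per-gene log-means by `N(0, shift_scale)` (plus
  optional multiplicative jitter) and counts are resampled, so batch
  structure is baked into the observed counts while all ground truth is
  kept.

What passing these benchmarks does *not* show: robustness to ambient RNA,
doublets, batch effects that interact with cell type, non-linear gene
programs, or accession-scale cell counts — the generator's noise is
independent across genes given the latent state, which is kinder than real
data.

## Numerical choices

* `acosh` arguments are clamped to `>= 1 + 1e-15`; Poincaré points are
  clipped to radius `(1 - 1e-5)/sqrt(K)` before distance evaluation.
* Möbius addition uses the gyrogroup sign convention (numerator coefficient
  `1 + 2K<x,y> + K|y|^2`), which satisfies `0 + x = x` and `(-x) + x = 0`;
  a sign-negated variant is kept behind a flag for sensitivity checks but
  fails the left-inverse identity.
* The kernel receives the *distance* (not its square) by default;
  `squared_input = TRUE` switches to squared arguments for sensitivity
  analysis.
* Distance gradients at coincident points (where the direction is
  undefined) are set to zero; denominators carry `1e-12`-type guards.
* Batch normalization uses momentum 0.1 running statistics (evaluation mode
  for all inference, so single cells embed fine); LeakyReLU slope is 0.01;
  Adam uses `(0.9, 0.999, 1e-8)`. Linear layers start at
  `U(-1/sqrt(fan_in), 1/sqrt(fan_in))`.
* Ties in k-NN search and co-ranking are broken by lower index, making
  every result deterministic given the seed.

## Evaluation criteria

`quality_scores()` implements the scale-independent co-ranking criteria:
the co-ranking matrix counts (high-rank, low-rank) co-occurrences; the
curve `Q_NX(K)` is the mass of its top-left `K x K` block over `K n`; the
scale is split at `argmax_K [Q_NX(K) - K/(n-1)]`; `Q_local` and `Q_global`
are the means of the curve on either side of the split. Low-dimensional
distances use the embedding's own metric (hyperbolic for hyperbolic
embeddings); high-dimensional distances are Euclidean on the model's input.
Inputs beyond 3000 cells are subsampled with a fixed seed (the co-ranking
matrix is O(n^2)). For batch-affected data, `per_batch_quality()` scores
each batch's cells separately against the *uncorrected* input.
`knn_transfer_accuracy()` (k = 5, majority vote, ties by smallest mean
distance) measures label transfer from a reference embedding;
`leave_one_group_out_accuracy()` averages it over held-out groups;
`batch_mixing()` normalizes the observed fraction of cross-batch neighbours
by its perfectly-mixed expectation.

## Known limitations

* Exact O(n^2) pairwise computations per minibatch bound practical batch
  sizes to a few thousand cells; very large datasets rely on minibatching.
* The loss is non-convex and the structure graph is itself learned;
  different seeds give visibly different layouts (the benchmarks therefore
  report medians over seeds).
* `K` is fixed, not learned; Lorentz formulas assume the unit hyperboloid
  convention for `K != 1` consistency (`K = 1` is the tested default).
* No early stopping: training runs for the configured number of epochs.
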