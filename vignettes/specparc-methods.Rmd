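---
title: "Methods: spatially constrained spectral parcellation and its evaluation"
author: "specparc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatially constrained spectral parcellation and its evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specparc)
```

# The problem

Voxel-level functional parcellation assigns every voxel of a masked brain
region — the motivating case is the cerebellum at 2 mm resolution — to one
of K functionally coherent, spatially contiguous subregions, using only
resting-state fMRI. A good parcellation is reproducible across subjects and
datasets, internally homogeneous in signal, spatially contiguous, and
available at whatever granularity K a downstream analysis needs. `specparc`
implements one family of methods with these four properties as explicit
targets, together with the metrics that measure them and a downstream
connectome-feature classifier.

# Similarity model

## Voxel functional connectivity

For voxels $i, j$ with time series $x_t, y_t$ ($t = 1..T$), functional
connectivity is the Pearson correlation

$$FC_{ij} = \frac{\sum_t (x_t - \bar x)(y_t - \bar y)}
  {\sqrt{\sum_t (x_t-\bar x)^2}\sqrt{\sum_t (y_t-\bar y)^2}}.$$

`extract_timeseries()` enumerates in-mask voxels in a fixed grid order
(x fastest, then y, then z); determinism of this order is load-bearing,
because all co-cluster matrices downstream index voxels by it.
Zero-variance voxels (possible at mask edges of preprocessed data) have no
defined correlation; the default drops them from the mask with a logged
count, and a strict mode errors instead. No temporal filtering or spatial
smoothing is applied anywhere in the package: inputs are assumed fully
preprocessed, and smoothing in particular would artificially inflate local
spatial correlation — exactly the signal this method clusters on.

## Spatial constraint

Clustering raw FC gives spatially fragmented parcels (distant voxels — e.g.
left/right homologues — correlate strongly). The similarity graph therefore
keeps only **positive** FC between voxels in each other's 26-neighbourhood
(all offsets in $\{-1,0,1\}^3$):

$$s_{ij} = f(\delta_{ij}(FC_{ij})), \qquad
\delta_{ij}(FC_{ij}) = \begin{cases} FC_{ij} & j \in U_i \text{ and } FC_{ij} > 0\\
0 & \text{otherwise.}\end{cases}$$

Negative correlations are discarded rather than interpreted. Absent entries
are never stored; a `radius` argument exposes larger neighbourhoods for
sensitivity analyses, with the 26-neighbourhood ($\sqrt 3$ radius) as the
default.

## Order-preserving transforms

The magnitude of a correlation is not a calibrated measure of connectivity
strength, but its rank order is more trustworthy. The retained values in
$(0,1]$ may therefore be reshaped by any strictly monotone
$f: [0,1]\to[0,1]$ with $f(0)=0$, $f(1)=1$:

| name | $f(x)$ | default | effect |
|---|---|---|---|
| origin | $x$ | — | reference (no change) |
| root | $(k+1)x/(1+kx)$ | $k=1$ | widens low/medium differences |
| square | $x^a$ | $a=2$ | widens medium/high differences, crushes small values |
| gaussian | $\frac{e^{-(x-1)^2/2\sigma^2}-e^{-1/2\sigma^2}}{1-e^{-1/2\sigma^2}}$ | $\sigma=1$ | smooths the distribution |

Because $f(0)=0$ and $f$ is strictly increasing, transforms never change
the sparsity pattern, only stored values. `validate_transform()` checks the
axioms numerically on a grid; hyperparameters are plain arguments, and
choosing among them is by sweeping the pipeline and comparing downstream
metrics, not by an internal optimizer.

# Partitioning

## Normalized cut

`spectral_partition()` minimizes the normalized-cut criterion on the sparse
similarity graph via the random-walk Laplacian $L_{rw} = I - D^{-1}W$. Two
variants are provided:

- **`recursive`** (default): repeated two-way cuts. Each candidate split
  computes the Fiedler vector of the current subgraph and sweeps every
  threshold along its sorted order, scoring each by the *exact* two-way
  ncut; the globally cheapest available split is applied until K clusters
  exist. This is deterministic (no random initialization) and each
  boundary gets a dedicated eigenproblem.
- **`kway`**: k-means on the rows of the K smallest eigenvectors of
  $L_{rw}$ (computed as the K largest of $D^{-1/2}WD^{-1/2}$, rescaled),
  with k-means++ initialization, seeded restarts, best
  within-cluster-sum-of-squares kept.

The recursive form is the default for two reasons observed directly on the
synthetic model. First, with K-way embedding a weak cut direction can be
displaced from the top-K eigenspace by a smooth *intra*-parcel mode when
eigenvalues nearly tie, after which no k-means labeling can recover the
lost boundary. Second, even with the correct subspace, the k-means
objective (spherical within-cluster variance) is not the ncut objective,
and prefers certain merge/split errors. The recursive sweep scores
candidate splits by the actual cut criterion, sidestepping both failure
modes. The k-way path is retained because it is the common modern form and
useful for cross-checking; k-means++ matters there — with K tight,
well-separated embedding clouds, uniformly sampled centers miss at least
one cloud with high probability and Lloyd iterations cannot recover.

Three practical rules complete the partitioner:

- If the graph has exactly K connected components, the components are
  returned directly; they are the exact optimum and the eigenbasis is
  indicator-spanned, so anything else is numerical noise.
- More components than K is an error (infeasible), reported with the count.
- Isolated voxels (no positive-FC neighbour) are excluded from the
  eigenproblem and attached afterwards to the cluster of the spatially
  nearest labeled voxel (Euclidean in mm; ties to the lowest label), with
  the count recorded.

Eigenproblems are solved densely up to a configurable size (default 2048
voxels) and by ARPACK (via `igraph`) above it; tiny subproblems always use
the dense path. The spectral machinery never sees the trivial eigenvector
problem: degree-zero rows are handled before it.

## Contiguity

The spatial constraint makes contiguous clusters overwhelmingly favourable
but the group-level consensus matrix (below) is not spatially supported, so
`contiguity_repair()` reports, per cluster, its number of connected
components in the neighbour graph, and can optionally repair: each
detached fragment is reassigned to the neighbouring cluster sharing the
most graph edges with it (ties to the lowest label), iterating until all
clusters are connected. Reporting is the default; repair is opt-in.

# Group-level ensemble

Individual parcellations disagree in labels and in detail. The group
partition is built in two levels:

1. cluster each subject's similarity matrix at K;
2. convert each subject's labels to the binary co-cluster
   ("adjacency representation") matrix $a_{ij} = 1$ iff $c_i = c_j$ (zero
   diagonal), average these across subjects into the consensus
   $S_G = \frac1N\sum_n AR_n$, and cluster $S_G$ itself at the same K.

The AR form is label-permutation invariant, which is the whole point: no
label matching across subjects is ever needed. The diagonal is kept at
zero everywhere, and the same convention is used by the AR-Dice metric, so
all-singleton partitions are an explicit undefined case rather than a
silent 1. $S_G$ is used as-is (no thresholding); it is accumulated as a
running sum so individual AR matrices are never all in memory.
`sweep_partitions()` runs the ensemble over K = 10..200 in steps of 5 (39
values) by default, recording infeasible K values (e.g. K larger than the
data supports, or K so close to n that individual partitions are
singleton-heavy and the consensus degenerates) instead of aborting.
`split_cohort()` provides the seeded 7:3 exploration/validation split used
by the reproducibility protocol (82 subjects split 57/25).

# Evaluation metrics

- **AR-Dice** (`dice_ar`): $2\sum_{ij} x_{ij}y_{ij} / (\sum x_{ij} + \sum
  y_{ij})$ over co-cluster matrices — the fraction of co-clustered voxel
  pairs two partitions share. Declines mechanically as K grows (fewer
  pairs), hence the complementary NMI.
- **NMI** (`nmi`): $2I(X,Y)/(H(X)+H(Y))$ from the empirical joint label
  distribution. Conventions: $0\log 0 = 0$; two single-cluster labelings
  give 1; exactly one single-cluster side gives 0.
- **IRH / AIRH** (`irh`, `airh`): a cluster's intraregional homogeneity is
  the mean Pearson correlation over its voxel pairs; AIRH is the
  cluster-size-weighted average over the mask. Singleton clusters have no
  pairs: they are excluded, counted, and the weights renormalized —
  defining their IRH as 1 would reward over-fragmentation.
- **Winner-take-all matching** (`winner_take_all_match`): each cluster is
  relabeled to the template label covering most of its voxels (ties to the
  lowest label; clusters wholly outside template coverage get 0 and are
  flagged), returning the overlap count matrix and per-template-label
  spatial Dice.

# Classification and region importance

`extract_region_fc()` averages the BOLD series within each of the N
regions of a partition and correlates region pairs, giving $N(N-1)/2$
features per subject in a fixed lexicographic pair order. Because
case/control cohorts often differ in age and sex, `confound_filter()`
excludes any feature whose Pearson correlation with age or Welch t-test
between sexes is significant at $\alpha = 0.05$. `fit_classifier_cv()`
z-scores features with training-fold statistics, fits an L2-regularized
logistic regression (penalty $1/(Cn)$, default $C = 1$) per stratified
fold, and reports held-out accuracy and ROC AUC across 5 folds. The filter
runs *within* training folds by default (no information leakage into the
held-out fold); a `whole_sample` mode reproduces the common
filter-then-cross-validate protocol for comparability.

Region importance aggregates fold coefficients as the mean absolute value,
scales by the maximum ($w' = |w|/\max|w|$ — implemented exactly in this
form), averages $w'$ over each region's $N-1$ incident pairs, and
renormalizes so the top region scores 1. The score is invariant to positive
rescaling of the coefficients.

# Synthetic data model

All tests run on generated data with known ground truth; nothing is
downloaded.

- **Planted parcels** (`make_planted_volume`): K seeds grow over the mask
  by synchronized region growing — each round every parcel claims the
  unassigned frontier voxel nearest its own seed — yielding compact,
  connected, roughly balanced parcels (connectivity-constrained Voronoi
  cells). Each parcel carries an i.i.d. Gaussian latent series; each voxel
  observes its parcel's latent plus i.i.d. Gaussian noise, so the expected
  within-parcel correlation is $\sigma_s^2/(\sigma_s^2+\sigma_n^2)$
  (0.8 at the default 2:1 signal-to-noise). Compactness is a deliberate
  modeling choice: with tangled or dumbbell-shaped parcels the planted
  truth stops being an optimum of the normalized-cut objective at all
  (an internal neck becomes as cheap to cut as a true boundary), and no
  boundary-cost method could or should recover it. Real functional
  subregions are blob-like at this scale.
- **Cohorts** (`make_cohort`): one shared parcel map, fresh latents and
  noise per subject, seeded per subject index. The degenerate
  shared-latent, zero-noise configuration produces identical subjects, for
  which the ensemble must return exactly each subject's partition.
- **Two-group feature cohorts** (`make_clf_cohort`): per-pair baselines
  plus Gaussian subject noise (sd 0.25); group 1 is shifted by
  `effect_size` (default 0.4, i.e. per-feature Cohen's d of 1.6) on 10
  affected pairs — a strongly separable planted effect, sized so the
  cross-validated estimator (not just the population optimum) detects it
  reliably at 60+60 subjects; optional age/sex leakage into a disjoint
  pair set tests the confound filter.

In the recovery harness the similarity uses the **square** transform: under
this generative model, between-parcel neighbour FC is pure sampling noise
of magnitude $\sim 1/\sqrt T$, and squaring suppresses it quadratically
relative to the $\approx 0.8$ within-parcel values, maximizing boundary
contrast. That choice is about the synthetic noise structure, not a general
recommendation: on real data the transform is exactly the knob a user
should sweep, and the root transform's expansion of low/medium contrasts
serves a different purpose there (separating moderate real coupling from
weak noise across subjects).

What the generator does *not* emulate: BOLD autocorrelation and
hemodynamics, physiological noise, motion artifacts, inter-subject
anatomical variability, or non-Gaussian FC distributions. Passing recovery
tests therefore demonstrates correctness of the machinery under the stated
model, not performance on real fMRI.

# Numerical choices and scales

- Eigensolver: dense symmetric eigendecomposition below 2048 voxels,
  ARPACK above (tolerance default 1e-8); recursive splits always solve
  small subproblems densely.
- All randomness (k-means restarts, generators, cohort splits) is behind
  explicit seeds; RNG state is saved and restored around every seeded
  operation, so library calls never perturb a caller's stream.
- Ties: fragment reassignment, isolated-voxel attachment and
  winner-take-all matching all break ties toward the lowest label;
  threshold ties in the Fiedler sweep resolve by voxel index.
- Degenerate inputs have defined behaviour: zero-variance voxels
  (drop/log or error), all-singleton partitions (AR-Dice NaN with
  warning), singleton clusters (excluded from homogeneity with
  renormalization), empty similarity rows (isolated-voxel path), constant
  features (degenerate-test flag, excluded).
- Test and verification scales: masks of 1–1.2k voxels (boxes from
  6×6×4 to 12×12×8), T = 10–500, cohorts of up to 8 subjects,
  feature cohorts of 120 subjects × 190 features. At these sizes the full
  suite and the acceptance script each run in a few minutes on one CPU.

# Limitations

- The group consensus matrix is dense in principle; masks far beyond ~10k
  voxels need the ARPACK path and patience, and very large K with the
  recursive method pays one eigenproblem per split.
- Near K ≈ n the co-association ensemble degenerates (singleton-heavy
  individual partitions); such K are reported infeasible.
- The confound filter is marginal (per-feature tests), not a joint
  deconfounding model; regression-based residualization is out of scope.
- No claim is made about the biological optimality of any K; the sweep
  plus metrics exist precisely because different uses favour different
  granularities.
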