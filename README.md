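# specparc

Spatially constrained spectral parcellation of masked fMRI volumes, with a
co-association group ensemble, parcellation quality metrics, and
connectome-feature classification.

## What problem this solves

Functional analyses of structures like the cerebellum need the voxels of a
masked region grouped into K spatially contiguous, functionally homogeneous
subregions — and K itself depends on the downstream question. `specparc`
builds such parcellations from preprocessed resting-state fMRI:

1. **Similarity.** Voxel-wise Pearson functional connectivity
   `FC_ij = cor(x_i, x_j)` is gated to positive values between
   26-neighbourhood voxels only (spatial constraint, which is what makes
   clusters contiguous) and optionally reshaped by an order-preserving
   transform `f` with `f(0)=0`, `f(1)=1`, strictly increasing:
   identity, `(k+1)x/(1+kx)` (root), `x^a` (square), or a rescaled
   Gaussian bump — the similarity is `s_ij = f(δ_ij(FC_ij))`.
2. **Partition.** Normalized-cut spectral clustering of the sparse
   similarity graph (random-walk Laplacian `I − D⁻¹W`). The default is the
   recursive two-way form — each split thresholds the Fiedler vector at
   the exact minimum two-way ncut — with a k-means-on-embedding variant
   available.
3. **Group ensemble.** Each subject's partition becomes a binary
   co-cluster (adjacency representation) matrix `a_ij = 1 ⟺ c_i = c_j`;
   their average across subjects is the group similarity
   `S_G = (1/N) Σ AR_n`, which is clustered at the same K. Label matching
   across subjects is never needed. A K-sweep (default 10..200 step 5)
   and a seeded 7:3 exploration/validation cohort split support the
   reproducibility protocol.
4. **Evaluation.** AR-Dice and NMI (partition agreement), IRH/AIRH
   (within-region signal homogeneity and its size-weighted average),
   winner-take-all matching against any template label map.
5. **Classification.** Region-pair FC features (`N(N−1)/2` per subject),
   age/sex confound filtering, L2 logistic regression with stratified
   5-fold CV (accuracy, AUC), and a per-region importance score
   `Imp̄_i` normalized so the top region is 1.

Every stage is also runnable against seed-deterministic synthetic data with
planted ground truth (`make_planted_volume`, `make_cohort`,
`make_clf_cohort`), so the full pipeline is testable without any external
data. I/O uses NIfTI-1 for volumes, masks and label maps, TSV/CSV for
matrices and metrics, JSON for configs and manifests.

## Worked example

```r
library(specparc)

# 1. synthetic cohort: 4 subjects, shared 6-parcel ground truth
spec <- planted_parcel_spec(dims = c(12, 12, 8), K_true = 6, T_len = 200, seed = 7)
cohort <- make_cohort(spec, n_subjects = 4)

# 2. per-subject similarity: spatial constraint + square transform
graph <- build_neighbor_graph(cohort$mask)
sims <- lapply(cohort$volumes, build_similarity, mask = cohort$mask,
               spec = transform_spec("square"), graph = graph)

# 3. two-level group ensemble at K = 6
res <- group_partition(sims, K = 6, seed = 1)
res$group
#> <partition> 1152 voxels in 6 clusters (sizes 186, 187, 193, 194, 194, 198)

# 4. agreement with the planted truth and across subjects
nmi(res$group, cohort$truth)
#> [1] 1
reproducibility(res$group, res$subjects)
#>   subject nmi dice
#> 1       1   1    1
#> 2       2   1    1
#> 3       3   1    1
#> 4       4   1    1

# 5. homogeneity of the group partition on subject 1
ts1 <- extract_timeseries(cohort$volumes[[1]], cohort$mask)
irh(ts1, res$group)
#> <homogeneity_report> AIRH = 0.8005 over 6 clusters (0 singletons excluded)

# 6. classification on a planted two-group cohort (60+60 subjects)
clf <- make_clf_cohort(clf_cohort_spec(seed = 11))
cv <- fit_classifier_cv(clf$ft, seed = 1)
cv
#> <cv_result> 5-fold CV: accuracy 0.967 +/- 0.035, AUC 0.989 +/- 0.016
imp <- region_importance(cv)
```

The group partition recovers the planted map exactly (NMI and Dice 1
against truth and every subject). The AIRH of 0.80 matches the generative
model: with a 2:1 signal-to-noise ratio the expected within-parcel
correlation is `1/(1+0.25) = 0.8`. The classifier separates the planted
group effect (AUC 0.99), and `imp$importance` puts the regions incident to
the affected FC pairs at the top.

A thin command-line interface wraps the same functions
(`exec/specparc`; subcommands `simulate`, `fc`, `partition`, `group`,
`sweep`, `evaluate`, `match`, `classify`), writing NIfTI/CSV artifacts, a
log and a JSON manifest per run.

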