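Package: specparc
Title: Spatially Constrained Spectral Parcellation of Masked fMRI Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Voxel-level functional parcellation of a masked brain region
    (e.g., the cerebellum) from resting-state fMRI. Builds a spatially
    constrained similarity graph from positive Pearson functional
    connectivity between 26-neighbourhood voxels, optionally reshaped by
    order-preserving transforms (root, square, gaussian), and partitions it
    with normalized-cut spectral clustering. Group parcellations are formed
    by a two-level cluster ensemble that averages binary co-cluster
    (adjacency representation) matrices across subjects. Includes
    reproducibility and homogeneity metrics (AR-Dice, NMI, IRH, AIRH),
    winner-take-all template matching, region-level connectivity feature
    extraction with confound-aware L2-regularized logistic regression, a
    region-importance score, and seed-deterministic synthetic data
    generators with planted ground-truth parcels.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    RNifti,
    igraph,
    glmnet,
    pROC,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
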