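#' Adjacency-representation (co-cluster) matrix of a partition
#'
#' Binary symmetric matrix with \eqn{a_{ij} = 1} iff voxels i and j share a
#' label, and a zero diagonal. The AR form is invariant to label
#' permutation, which is what makes partitions from different subjects
#' comparable without label matching.
#'
#' @param p a `partition` or a bare label vector.
#' @return An object of class `ar_matrix`: `n`, `mat` (sparse symmetric 0/1,
#'   zero diagonal).
#' @export
to_adjacency <- function(p) {
  labels <- if (inherits(p, "partition")) p$labels else as.integer(p)
  n <- length(labels)
  K <- max(labels)
  Z <- Matrix::sparseMatrix(i = seq_len(n), j = labels, x = 1,
                            dims = c(n, K))
  A <- Matrix::tcrossprod(Z)
  Matrix::diag(A) <- 0
  structure(list(n = n, mat = Matrix::drop0(A)), class = "ar_matrix")
}

#' @export
print.ar_matrix <- function(x, ...) {
  cat(sprintf("<ar_matrix> %d voxels, %d co-clustered pairs\n",
              x$n, Matrix::nnzero(x$mat) / 2))
  invisible(x)
}

#' Recover a partition's labels from its AR matrix
#'
#' Connected components of the co-cluster graph; inverse of [to_adjacency()]
#' up to label permutation.
#'
#' @param ar an `ar_matrix`.
#' @return integer label vector.
#' @export
adjacency_to_labels <- function(ar) {
  g <- igraph::graph_from_adjacency_matrix(ar$mat > 0, mode = "undirected")
  canonical_labels(as.integer(igraph::components(g)$membership))
}

#' Group similarity: entrywise mean of co-cluster matrices
#'
#' The co-association consensus: entry (i, j) is the fraction of subjects in
#' which voxels i and j share a cluster. Accumulated as a running sum so the
#' individual AR matrices are never all held at once.
#'
#' @param ars a list of `ar_matrix` (or `partition`) objects on the same n.
#' @param mask optional [voxel_mask()] carried into the group eigenproblem.
#' @return An object of class `group_similarity`: `n`, `mat` (entries in
#'   `[0, 1]`, zero diagonal), `n_subjects`, `mask`.
#' @export
group_similarity <- function(ars, mask = NULL) {
  if (length(ars) == 0L) stop("empty list of AR matrices")
  ars <- lapply(ars, function(a) if (inherits(a, "partition")) to_adjacency(a) else a)
  n <- ars[[1]]$n
  acc <- NULL
  for (a in ars) {
    stopifnot(inherits(a, "ar_matrix"))
    if (a$n != n) stop("AR matrices have mismatched sizes: ", a$n, " vs ", n)
    acc <- if (is.null(acc)) a$mat else acc + a$mat
  }
  structure(list(n = n, mat = acc / length(ars), n_subjects = length(ars),
                 mask = mask),
            class = "group_similarity")
}

#' @export
print.group_similarity <- function(x, ...) {
  cat(sprintf("<group_similarity> %d voxels, consensus of %d subjects\n",
              x$n, x$n_subjects))
  invisible(x)
}

#' Two-level group clustering ensemble
#'
#' The group pipeline: spectrally cluster each subject's similarity matrix
#' at K, convert each partition to its co-cluster (AR) matrix, average the
#' AR matrices into the group similarity, and spectrally cluster that at the
#' same K.
#'
#' @param subject_similarities list of `sparse_similarity`, one per subject,
#'   all on the same mask.
#' @param K number of clusters.
#' @param cfg a [spectral_config()]; default uses `K` and `seed`.
#' @param seed seed used when `cfg` is NULL.
#' @return list with `group` (the group `partition`), `subjects` (list of
#'   per-subject `partition`s), `consensus` (the `group_similarity`).
#' @export
group_partition <- function(subject_similarities, K, cfg = NULL, seed = 1) {
  if (length(subject_similarities) == 0L) stop("need at least one subject")
  if (is.null(cfg)) cfg <- spectral_config(K, seed = seed)
  mask <- subject_similarities[[1]]$mask
  subjects <- vector("list", length(subject_similarities))
  acc <- NULL
  for (i in seq_along(subject_similarities)) {
    s <- subject_similarities[[i]]
    if (!identical(s$mask$linear, mask$linear))
      stop("subject ", i, " is on a different mask")
    subjects[[i]] <- spectral_partition(s, cfg)
    ar <- to_adjacency(subjects[[i]])
    acc <- if (is.null(acc)) ar$mat else acc + ar$mat
  }
  consensus <- structure(list(n = mask$n, mat = acc / length(subjects),
                              n_subjects = length(subjects), mask = mask),
                         class = "group_similarity")
  group <- spectral_partition(consensus, cfg)
  list(group = group, subjects = subjects, consensus = consensus)
}

#' Enumerate the K values of a sweep
#'
#' @param k_min,k_max,step arithmetic sequence parameters; defaults are the
#'   standard sweep K = 10..200 in steps of 5 (39 values).
#' @return integer vector of K values.
#' @export
sweep_plan <- function(k_min = 10, k_max = 200, step = 5) {
  stopifnot(k_min <= k_max, step >= 1)
  seq.int(as.integer(k_min), as.integer(k_max), by = as.integer(step))
}

#' Group partitions across a sweep of K
#'
#' Runs [group_partition()] at each K in the sweep. K values exceeding what
#' the data supports are recorded as infeasible rather than aborting the
#' sweep.
#'
#' @inheritParams sweep_plan
#' @param subject_similarities list of per-subject `sparse_similarity`.
#' @param cfg_fn function K -> [spectral_config()]; default uses `seed`.
#' @param seed seed for the default `cfg_fn`.
#' @return list with `partitions` (named list, one group `partition` per
#'   feasible K), `infeasible` (named character vector of messages), `plan`.
#' @export
sweep_partitions <- function(subject_similarities, k_min = 10, k_max = 200,
                             step = 5, cfg_fn = NULL, seed = 1) {
  ks <- sweep_plan(k_min, k_max, step)
  if (is.null(cfg_fn)) cfg_fn <- function(K) spectral_config(K, seed = seed)
  partitions <- list()
  infeasible <- character(0)
  for (K in ks) {
    res <- tryCatch(group_partition(subject_similarities, K, cfg = cfg_fn(K)),
                    error = function(e) e)
    if (inherits(res, "error")) {
      infeasible[as.character(K)] <- conditionMessage(res)
    } else {
      partitions[[as.character(K)]] <- res$group
    }
  }
  list(partitions = partitions, infeasible = infeasible, plan = ks)
}

#' Split a cohort into exploration and validation sets
#'
#' Seeded shuffle of subject ids; the validation side gets
#' `round((1 - ratio) * N)` subjects and the exploration side the remainder
#' (82 subjects at ratio 0.7 gives 57 / 25).
#'
#' @param subject_ids vector of ids, length >= 2.
#' @param ratio_exploration exploration fraction in (0, 1); default 0.7.
#' @param seed RNG seed.
#' @return An object of class `cohort_split` with `exploration_ids`,
#'   `validation_ids`, `seed`.
#' @export
split_cohort <- function(subject_ids, ratio_exploration = 0.7, seed = 1) {
  n <- length(subject_ids)
  stopifnot(n >= 2, ratio_exploration > 0, ratio_exploration < 1)
  n_val <- round((1 - ratio_exploration) * n)
  if (n_val == 0L || n_val == n)
    stop("split ratio ", ratio_exploration, " leaves one side empty for n = ", n)
  perm <- with_seed(seed, sample.int(n))
  structure(list(exploration_ids = subject_ids[sort(perm[seq_len(n - n_val)])],
                 validation_ids = subject_ids[sort(perm[seq.int(n - n_val + 1L, n)])],
                 seed = as.integer(seed)),
            class = "cohort_split")
}

#' @export
print.cohort_split <- function(x, ...) {
  cat(sprintf("<cohort_split> %d exploration / %d validation (seed %d)\n",
              length(x$exploration_ids), length(x$validation_ids), x$seed))
  invisible(x)
}
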