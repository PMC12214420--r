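test_that("adjacency representation matches the co-cluster definition", {
  ar <- to_adjacency(c(1L, 1L, 2L))
  M <- as.matrix(ar$mat)
  expect_equal(M, matrix(c(0, 1, 0, 1, 0, 0, 0, 0, 0), 3, 3))

  all_one <- to_adjacency(rep(1L, 4))
  expect_equal(sum(all_one$mat), 12)            # all off-diagonal entries
  expect_equal(unname(diag(as.matrix(all_one$mat))), rep(0, 4))

  all_distinct <- to_adjacency(1:5)
  expect_equal(sum(all_distinct$mat), 0)
})

test_that("AR is label-permutation invariant and recoverable", {
  set.seed(31)
  for (r in 1:20) {
    labels <- random_labels(25, sample(2:6, 1))
    perm <- sample(max(labels))
    ar1 <- to_adjacency(labels)
    ar2 <- to_adjacency(perm[labels])
    expect_identical(as.matrix(ar1$mat), as.matrix(ar2$mat))
    rec <- adjacency_to_labels(ar1)
    expect_equal(nmi(rec, labels), 1)
  }
})

test_that("group similarity is the co-clustering fraction across subjects", {
  ars <- list(to_adjacency(c(1L, 1L, 2L)), to_adjacency(c(1L, 2L, 2L)))
  sg <- group_similarity(ars)
  M <- as.matrix(sg$mat)
  expect_equal(M[1, 2], 0.5)
  expect_equal(M[2, 3], 0.5)
  expect_equal(M[1, 3], 0)
  expect_equal(sg$n_subjects, 2L)

  # identical ARs average to themselves
  same <- group_similarity(list(ars[[1]], ars[[1]], ars[[1]]))
  expect_equal(as.matrix(same$mat), as.matrix(ars[[1]]$mat))

  # brute-force fraction oracle on random cohorts
  set.seed(33)
  for (r in 1:10) {
    labs <- lapply(1:7, function(i) random_labels(12, 3))
    sg <- group_similarity(lapply(labs, to_adjacency))
    M <- as.matrix(sg$mat)
    for (i in 1:11) for (j in (i + 1):12) {
      frac <- mean(vapply(labs, function(l) l[i] == l[j], logical(1)))
      expect_equal(M[i, j], frac, tolerance = 1e-12)
    }
  }
  expect_error(group_similarity(list()), "empty")
  expect_error(group_similarity(list(to_adjacency(c(1L, 2L)),
                                     to_adjacency(c(1L, 1L, 2L)))), "mismatch")
})

test_that("adding a consensus-identical subject never lowers consensus entries", {
  set.seed(35)
  labs <- lapply(1:5, function(i) random_labels(15, 3))
  consensus <- random_labels(15, 3)
  sg1 <- group_similarity(lapply(labs, to_adjacency))
  sg2 <- group_similarity(lapply(c(labs, list(consensus)), to_adjacency))
  ar_c <- as.matrix(to_adjacency(consensus)$mat)
  on_consensus <- ar_c > 0
  expect_true(all(as.matrix(sg2$mat)[on_consensus] >=
                  as.matrix(sg1$mat)[on_consensus] - 1e-12))
})

test_that("single-subject ensemble reproduces that subject's partition", {
  spec <- planted_parcel_spec(dims = c(8, 8, 5), K_true = 4, seed = 41)
  coh <- make_cohort(spec, n_subjects = 1)
  s <- build_similarity(coh$volumes[[1]], coh$mask, spec = transform_spec("square"))
  res <- group_partition(list(s), K = 4, seed = 1)
  expect_equal(nmi(res$group, res$subjects[[1]]), 1)
})

test_that("group ensemble recovers a shared planted map from a noisy cohort", {
  spec <- planted_parcel_spec(dims = c(10, 10, 6), K_true = 5, seed = 43)
  coh <- make_cohort(spec, n_subjects = 5)
  g <- build_neighbor_graph(coh$mask)
  sims <- lapply(coh$volumes, build_similarity, mask = coh$mask,
                 spec = transform_spec("square"), graph = g)
  res <- group_partition(sims, K = 5, seed = 1)
  expect_gte(nmi(res$group, coh$truth), 0.95)
  # consensus entries are subject fractions
  expect_true(all(as.matrix(res$consensus$mat) %in% ((0:5) / 5)))
})

test_that("independent random partitions yield a weaker group consensus", {
  set.seed(45)
  n <- 200
  mask <- voxel_mask(array(TRUE, dim = c(n, 1, 1)))
  rand_parts <- lapply(1:6, function(i) new_partition(random_labels(n, 5), mask))
  sg_rand <- group_similarity(rand_parts, mask = mask)
  g_rand <- spectral_partition(sg_rand, K = 5, seed = 1)
  nmi_rand <- mean(vapply(rand_parts, function(p) nmi(g_rand, p), numeric(1)))

  shared <- new_partition(random_labels(n, 5), mask)
  sg_same <- group_similarity(rep(list(shared), 6), mask = mask)
  g_same <- spectral_partition(sg_same, K = 5, seed = 1)
  nmi_same <- mean(nmi(g_same, shared))
  expect_lt(nmi_rand, nmi_same - 0.2)
  expect_equal(nmi_same, 1)
})

test_that("sweep plan and sweep execution follow the arithmetic sequence", {
  expect_length(sweep_plan(), 39)
  expect_equal(sweep_plan(10, 10, 5), 10L)
  expect_equal(sweep_plan(10, 20, 5), c(10L, 15L, 20L))

  # tiny instance: 18 voxels on a line with strongly positive FC so the
  # similarity graph is connected; K = 20 exceeds the voxel count
  set.seed(47)
  n <- 18
  mask <- voxel_mask(array(TRUE, dim = c(n, 1, 1)))
  latent <- rnorm(40)
  values <- matrix(rep(latent, each = n), n, 40) + 0.05 * matrix(rnorm(n * 40), n, 40)
  s <- spatial_constrain(pearson_fc(ts_from_matrix(values, mask)),
                         build_neighbor_graph(mask))
  sw <- sweep_partitions(list(s), k_min = 10, k_max = 20, step = 5, seed = 1)
  expect_setequal(names(sw$partitions), "10")
  # K = 15 leaves the co-association consensus degenerate (singleton-heavy
  # individual partitions), K = 20 exceeds the voxel count; both are
  # recorded rather than fatal
  expect_setequal(names(sw$infeasible), c("15", "20"))
})

test_that("cohort split honours the ratio and is seed deterministic", {
  ids <- sprintf("sub%03d", 1:82)
  sp <- split_cohort(ids, 0.7, seed = 4)
  expect_length(sp$exploration_ids, 57)
  expect_length(sp$validation_ids, 25)
  expect_length(intersect(sp$exploration_ids, sp$validation_ids), 0)
  expect_setequal(c(sp$exploration_ids, sp$validation_ids), ids)

  sp2 <- split_cohort(ids, 0.7, seed = 4)
  expect_identical(sp$exploration_ids, sp2$exploration_ids)
  sp3 <- split_cohort(1:10, 0.7, seed = 1)
  expect_length(sp3$exploration_ids, 7)
  expect_length(sp3$validation_ids, 3)
  expect_error(split_cohort(1:10, 0.999, seed = 1), "empty")
})
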