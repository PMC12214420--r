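test_that("AR-Dice hand case and boundary cases", {
  expect_equal(dice_ar(c(1, 1, 2, 2), c(1, 1, 1, 2)), 0.4)
  expect_equal(dice_ar(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(dice_ar(c(1, 1, 2, 2), c(1, 2, 1, 2)), 0)  # no shared pair
  expect_warning(d <- dice_ar(1:4, 1:4), "all-singletons")
  expect_true(is.nan(d))
})

test_that("NMI hand cases and degenerate conventions", {
  expect_equal(nmi(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(nmi(c(1, 1, 2, 2), c(1, 2, 1, 2)), 0)  # independent joint
  expect_equal(nmi(rep(1, 5), rep(1, 5)), 1)          # both single-cluster
  expect_equal(nmi(rep(1, 6), c(1, 1, 2, 2, 3, 3)), 0) # one trivial side
})

test_that("dice and nmi match brute-force oracles on random pairs", {
  set.seed(51)
  for (r in 1:100) {
    n <- sample(6:30, 1)  # n > K so at least one co-clustered pair exists
    lx <- random_labels(n, sample(2:5, 1))
    ly <- random_labels(n, sample(2:5, 1))
    expect_equal(dice_ar(lx, ly), oracle_dice(lx, ly), tolerance = 1e-12)
    expect_equal(nmi(lx, ly), oracle_nmi(lx, ly), tolerance = 1e-12)
  }
})

test_that("dice and nmi are invariant under label permutation", {
  set.seed(53)
  for (r in 1:25) {
    n <- sample(10:30, 1)
    lx <- random_labels(n, 4)
    ly <- random_labels(n, 3)
    px <- sample(4)[lx]
    py <- sample(3)[ly]
    expect_equal(dice_ar(px, py), dice_ar(lx, ly), tolerance = 1e-12)
    expect_equal(nmi(px, py), nmi(lx, ly), tolerance = 1e-12)
    expect_equal(nmi(lx, px), 1)
  }
})

test_that("IRH per-cluster values match pairwise-correlation means", {
  set.seed(55)
  mask <- voxel_mask(array(TRUE, dim = c(6, 1, 1)))
  values <- matrix(rnorm(6 * 40), 6, 40)
  ts <- ts_from_matrix(values, mask)
  p <- new_partition(c(1L, 1L, 1L, 2L, 2L, 2L), mask)
  rep <- irh(ts, p)
  r12 <- oracle_pearson(values[1, ], values[2, ])
  r13 <- oracle_pearson(values[1, ], values[3, ])
  r23 <- oracle_pearson(values[2, ], values[3, ])
  expect_equal(rep$per_cluster$irh[1], mean(c(r12, r13, r23)), tolerance = 1e-12)

  # a shared time course gives IRH exactly 1
  shared <- matrix(rep(rnorm(40), each = 3), 3, 40)
  ts2 <- ts_from_matrix(rbind(shared, values[4:6, ]), mask)
  rep2 <- irh(ts2, p)
  expect_equal(rep2$per_cluster$irh[1], 1, tolerance = 1e-12)
})

test_that("an independent-noise cluster has IRH near zero", {
  set.seed(57)
  mask <- voxel_mask(array(TRUE, dim = c(50, 1, 1)))
  values <- matrix(rnorm(50 * 200), 50, 200)
  rep <- irh(ts_from_matrix(values, mask), new_partition(rep(1L, 50), mask))
  expect_lt(abs(rep$per_cluster$irh[1]), 0.05)
})

test_that("AIRH is the size-weighted IRH mean and matches the expanded form", {
  # hand-weighted mean: sizes 10 and 30, IRH 0.8 and 0.4 -> 0.5
  per <- c(0.8, 0.4)
  w <- c(10, 30) / 40
  expect_equal(sum(w * per), 0.5)

  set.seed(59)
  for (r in 1:50) {
    n <- sample(8:16, 1)
    K <- sample(2:3, 1)
    labels <- random_labels(n, K)
    while (min(tabulate(labels)) < 2)  # expanded-form oracle assumes no singletons
      labels <- random_labels(n, K)
    values <- matrix(rnorm(n * 20), n, 20)
    mask <- voxel_mask(array(TRUE, dim = c(n, 1, 1)))
    a <- airh(ts_from_matrix(values, mask), new_partition(labels, mask))
    expect_equal(a, oracle_airh(values, labels), tolerance = 1e-10)
  }
})

test_that("AIRH excludes singleton clusters with renormalized weights", {
  set.seed(61)
  mask <- voxel_mask(array(TRUE, dim = c(5, 1, 1)))
  values <- matrix(rnorm(5 * 30), 5, 30)
  labels <- c(1L, 1L, 2L, 2L, 3L)  # cluster 3 is a singleton
  rep <- irh(ts_from_matrix(values, mask), new_partition(labels, mask))
  expect_equal(rep$excluded_singletons, 1L)
  expect_true(is.na(rep$per_cluster$irh[3]))
  w <- c(2, 2) / 4
  expect_equal(rep$airh, sum(w * rep$per_cluster$irh[1:2]), tolerance = 1e-12)
})

test_that("homogeneity of internally identical clusters is exactly 1", {
  set.seed(63)
  mask <- voxel_mask(array(TRUE, dim = c(9, 1, 1)))
  latent <- matrix(rnorm(3 * 25), 3, 25)
  labels <- rep(1:3, each = 3L)
  values <- latent[labels, ]
  a <- airh(ts_from_matrix(values, mask), new_partition(labels, mask))
  expect_equal(a, 1, tolerance = 1e-12)
})

test_that("winner-take-all matching: self, majority and tie cases", {
  mask <- voxel_mask(array(TRUE, dim = c(10, 1, 1)))
  p <- new_partition(rep(1:2, each = 5L), mask)
  self <- winner_take_all_match(p, p)
  expect_equal(self$mapping, 1:2)
  expect_equal(self$relabeled, p$labels)
  expect_equal(unname(diag(self$overlap)), c(5, 5))
  expect_equal(unname(self$template_dice), c(1, 1))

  # cluster of 10 voxels: 6 under template A(=1), 4 under B(=2)
  p2 <- new_partition(rep(1L, 10), mask, K = 1)
  tmpl <- c(rep(1L, 6), rep(2L, 4))
  m2 <- winner_take_all_match(p2, tmpl)
  expect_equal(m2$mapping, 1L)

  # exact 5/5 tie goes to the lower template label
  tmpl_tie <- rep(c(1L, 2L), each = 5L)
  m3 <- winner_take_all_match(p2, tmpl_tie)
  expect_equal(m3$mapping, 1L)

  # cluster fully outside template coverage is flagged 0
  tmpl0 <- c(rep(0L, 5), rep(3L, 5))
  m4 <- winner_take_all_match(p, tmpl0)
  expect_equal(m4$mapping, c(0L, 3L))
  expect_equal(m4$unmatched, 1L)
})

test_that("overlap rows sum to cluster sizes", {
  set.seed(65)
  mask <- voxel_mask(array(TRUE, dim = c(40, 1, 1)))
  p <- new_partition(random_labels(40, 4), mask)
  tmpl <- random_labels(40, 3)
  m <- winner_take_all_match(p, tmpl)
  expect_equal(unname(rowSums(m$overlap)), tabulate(p$labels, 4))
})

test_that("reproducibility harness ranks matched cohorts above mismatched ones", {
  spec <- planted_parcel_spec(dims = c(8, 8, 5), K_true = 4, seed = 67)
  coh <- make_cohort(spec, n_subjects = 4)
  g <- build_neighbor_graph(coh$mask)
  sims <- lapply(coh$volumes, build_similarity, mask = coh$mask,
                 spec = transform_spec("square"), graph = g)
  res <- group_partition(sims, K = 4, seed = 1)
  rep_same <- reproducibility(res$group, res$subjects)
  expect_true(all(rep_same$nmi >= 0 & rep_same$nmi <= 1))
  expect_true(all(rep_same$dice >= 0 & rep_same$dice <= 1))

  other <- make_cohort(planted_parcel_spec(dims = c(8, 8, 5), K_true = 4,
                                           seed = 97), n_subjects = 4)
  sims_o <- lapply(other$volumes, build_similarity, mask = other$mask,
                   spec = transform_spec("square"), graph = g)
  res_o <- group_partition(sims_o, K = 4, seed = 1)
  rep_cross <- reproducibility(res_o$group, res$subjects)
  expect_gt(mean(rep_same$nmi), mean(rep_cross$nmi))
})
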