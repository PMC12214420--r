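test_that("region pair index is a stable bijection", {
  idx <- region_pair_index(10)
  expect_equal(nrow(idx), 45)
  expect_equal(idx$column, seq_len(45))
  # round trip: column -> pair -> column
  for (m in idx$column) {
    found <- which(idx$i == idx$i[m] & idx$j == idx$j[m])
    expect_equal(found, m)
  }
  expect_equal(idx$i[1:3], c(1L, 1L, 1L))
  expect_equal(idx$j[1:3], c(2L, 3L, 4L))
})

test_that("region FC features follow the pair ordering and known values", {
  spec <- planted_parcel_spec(dims = c(6, 6, 4), K_true = 2, T_len = 50,
                              noise_sd = 0, seed = 71)
  pv <- make_planted_volume(spec)
  ts <- extract_timeseries(pv$volume, pv$mask)
  f2 <- extract_region_fc(ts, pv$truth)
  expect_length(f2, 1)  # N = 2 -> a single pair

  # two clusters sharing one latent time course correlate exactly 1
  mask <- voxel_mask(array(TRUE, dim = c(4, 1, 1)))
  latent <- rnorm(30)
  values <- rbind(latent, latent + 0, latent, latent)
  p <- new_partition(c(1L, 1L, 2L, 2L), mask)
  f <- extract_region_fc(specparc:::new_timeseries(values, mask), p)
  expect_equal(unname(f), 1, tolerance = 1e-12)

  spec10 <- planted_parcel_spec(dims = c(8, 8, 5), K_true = 10, seed = 73)
  pv10 <- make_planted_volume(spec10)
  f10 <- extract_region_fc(extract_timeseries(pv10$volume, pv10$mask), pv10$truth)
  expect_length(f10, 45)
  expect_equal(names(f10)[1:2], c("fc_1_2", "fc_1_3"))
})

test_that("confound filter excludes covariate-linked features and is calibrated", {
  coh <- make_clf_cohort(clf_cohort_spec(confound_strength = 0.5, seed = 75))
  cf <- confound_filter(coh$ft)
  expect_true(all(!cf$keep[coh$confound_columns]))

  # pure-noise calibration: exclusion fraction ~ 1 - (1 - alpha)^2
  set.seed(77)
  n <- 200; M <- 2000
  X <- matrix(rnorm(n * M), n, M)
  ft <- feature_table(X, group = rep(0:1, each = n / 2),
                      age = rnorm(n, 60, 8), sex = rbinom(n, 1, 0.5),
                      pair_index = data.frame(column = seq_len(M),
                                              i = rep(1L, M), j = seq_len(M) + 1L))
  cf2 <- confound_filter(ft)
  expect_lt(abs(cf2$n_excluded / M - (1 - 0.95^2)), 0.03)

  # no covariates: vacuous with a warning
  ft0 <- feature_table(X[, 1:10], group = rep(0:1, each = n / 2))
  expect_warning(cf3 <- confound_filter(ft0), "vacuous")
  expect_true(all(cf3$keep))

  # constant feature flagged degenerate and excluded
  Xc <- X[, 1:5]; Xc[, 3] <- 1
  ftc <- feature_table(Xc, group = rep(0:1, each = n / 2),
                       age = rnorm(n), sex = rbinom(n, 1, 0.5),
                       pair_index = data.frame(column = 1:5, i = rep(1L, 5), j = 2:6))
  cfc <- confound_filter(ftc)
  expect_true(cfc$degenerate[3])
  expect_false(cfc$keep[3])
})

test_that("classifier separates a planted effect and collapses under permutation", {
  coh <- make_clf_cohort(clf_cohort_spec(seed = 79))
  cv <- fit_classifier_cv(coh$ft, seed = 1)
  expect_gte(cv$mean_auc, 0.9)
  expect_equal(nrow(cv$per_fold), 5L)
  expect_true(all(cv$per_fold$auc >= 0 & cv$per_fold$auc <= 1))
  expect_true(all(cv$per_fold$accuracy >= 0 & cv$per_fold$accuracy <= 1))

  perm_auc <- mean(vapply(1:3, function(p) {
    ftp <- coh$ft
    set.seed(800 + p)
    ftp$group <- sample(ftp$group)
    fit_classifier_cv(ftp, seed = 1)$mean_auc
  }, numeric(1)))
  expect_gte(perm_auc, 0.35)
  expect_lte(perm_auc, 0.65)
})

test_that("duplicating every subject leaves fold accuracy approximately unchanged", {
  coh <- make_clf_cohort(clf_cohort_spec(n_per_group = c(30, 30), seed = 81))
  cv1 <- fit_classifier_cv(coh$ft, seed = 1)
  ft2 <- feature_table(rbind(coh$ft$features, coh$ft$features),
                       group = c(coh$ft$group, coh$ft$group),
                       age = c(coh$ft$age, coh$ft$age),
                       sex = c(coh$ft$sex, coh$ft$sex),
                       pair_index = coh$ft$pair_index)
  cv2 <- fit_classifier_cv(ft2, seed = 1)
  expect_lt(abs(cv1$mean_accuracy - cv2$mean_accuracy), 0.15)
})

test_that("whole-sample filter scope reproduces the pre-CV filtering protocol", {
  coh <- make_clf_cohort(clf_cohort_spec(confound_strength = 0.6, seed = 83))
  cv <- fit_classifier_cv(coh$ft, seed = 1, filter_scope = "whole_sample")
  # leaked columns carry zero coefficients in every fold
  expect_true(all(cv$coefficients[, coh$confound_columns] == 0))
  expect_true(all(!cv$keep[, coh$confound_columns]))
})

test_that("single-class input and undersized folds error", {
  coh <- make_clf_cohort(clf_cohort_spec(seed = 85))
  ft <- coh$ft
  ft$group <- rep(0L, length(ft$group))
  expect_error(fit_classifier_cv(ft, seed = 1), "both classes")
  ft2 <- coh$ft
  expect_error(fit_classifier_cv(ft2, folds = 80, seed = 1), "fewer subjects")
})

test_that("region importance algebra matches the hand cases", {
  idx <- region_pair_index(5)
  w <- rep(0, nrow(idx))
  w[1] <- 0.7  # pair (1,2) only
  imp <- region_importance(w, idx)
  expect_equal(imp$importance, c(1, 1, 0, 0, 0))

  imp_eq <- region_importance(rep(0.3, nrow(idx)), idx)
  expect_equal(imp_eq$importance, rep(1, 5))
  expect_equal(max(imp_eq$importance), 1)
  expect_error(region_importance(rep(0, nrow(idx)), idx), "all coefficients")
})

test_that("importance is invariant to positive rescaling of coefficients", {
  set.seed(87)
  idx <- region_pair_index(8)
  w <- rnorm(nrow(idx))
  i1 <- region_importance(w, idx)
  i2 <- region_importance(w * 37.5, idx)
  expect_equal(i1$importance, i2$importance, tolerance = 1e-12)
})

test_that("affected regions rank above unaffected ones in importance", {
  coh <- make_clf_cohort(clf_cohort_spec(seed = 89))
  cv <- fit_classifier_cv(coh$ft, seed = 1)
  expect_gte(cv$mean_auc, 0.8)
  imp <- region_importance(cv)
  aff <- coh$affected_regions
  expect_gt(mean(imp$importance[aff]), mean(imp$importance[-aff]))
})

test_that("importance is stable across independent cohorts with the same effect", {
  aff <- as.matrix(region_pair_index(20)[1:10, c("i", "j")])
  imps <- lapply(c(95, 96), function(sd) {
    coh <- make_clf_cohort(clf_cohort_spec(affected_pairs = aff, seed = sd))
    region_importance(fit_classifier_cv(coh$ft, seed = 1))$importance
  })
  expect_gt(stats::cor(imps[[1]], imps[[2]]), 0)
})

test_that("feature tables round-trip through CSV", {
  coh <- make_clf_cohort(clf_cohort_spec(n_per_group = c(12, 12), N_regions = 6,
                                         seed = 93))
  path <- tempfile(fileext = ".csv")
  write_feature_csv(coh$ft, path)
  ft2 <- read_feature_csv(path)
  expect_equal(ft2$features, coh$ft$features, tolerance = 1e-12)
  expect_equal(ft2$group, coh$ft$group)
  expect_equal(ft2$age, coh$ft$age, tolerance = 1e-12)
  expect_equal(ft2$N, coh$ft$N)
})
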