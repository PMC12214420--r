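#' Region-pair index for N regions
#'
#' The fixed feature ordering: unordered pairs (i, j), i < j, ordered
#' lexicographically by i then j. Column m of a feature matrix always maps
#' to the same pair and back.
#'
#' @param N number of regions, >= 2.
#' @return data frame with columns `column`, `i`, `j` (M = N(N-1)/2 rows).
#' @export
region_pair_index <- function(N) {
  stopifnot(N >= 2)
  i <- rep(seq_len(N - 1), times = (N - 1):1)
  j <- unlist(lapply(seq_len(N - 1), function(a) (a + 1):N))
  data.frame(column = seq_along(i), i = i, j = j)
}

#' Region-level FC features from a partition
#'
#' Averages the BOLD time series over each cluster, correlates every pair
#' of cluster means, and vectorizes the upper triangle in
#' [region_pair_index()] order — the N(N-1)/2 connectivity features used by
#' the classifier.
#'
#' @param ts a `timeseries_matrix`.
#' @param p a `partition` with N >= 2 clusters on the same mask.
#' @return named numeric vector of length N(N-1)/2 (`fc_i_j` names).
#' @export
extract_region_fc <- function(ts, p) {
  stopifnot(inherits(ts, "timeseries_matrix"), inherits(p, "partition"))
  if (!identical(ts$mask$linear, p$mask$linear))
    stop("time series and partition are on different masks")
  if (p$K < 2) stop("need at least 2 regions")
  means <- rowsum(ts$values, p$labels) / as.vector(tabulate(p$labels, p$K))
  v <- rowvar(means)
  if (any(v <= 0))
    stop("region ", which(v <= 0)[1], " has a zero-variance mean series; FC undefined")
  R <- stats::cor(t(means))
  idx <- region_pair_index(p$K)
  out <- R[cbind(idx$i, idx$j)]
  names(out) <- paste0("fc_", idx$i, "_", idx$j)
  out
}

#' Feature table for classification
#'
#' Subjects x region-pair FC features with group labels and age/sex
#' covariates.
#'
#' @param features numeric matrix, subjects x M, M = N(N-1)/2.
#' @param group binary group label per subject (0/1, logical, or 2-level
#'   factor).
#' @param age numeric per subject, or `NULL`.
#' @param sex binary per subject (0/1), or `NULL`.
#' @param subjects subject ids; default `1..n`.
#' @param pair_index a [region_pair_index()]; inferred from M when `NULL`.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(features, group, age = NULL, sex = NULL,
                          subjects = NULL, pair_index = NULL) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (is.factor(group) || is.character(group)) group <- as.integer(factor(group)) - 1L
  group <- as.integer(group)
  stopifnot(length(group) == n, all(group %in% c(0L, 1L)))
  if (anyNA(features)) stop("feature table contains missing values")
  if (is.null(pair_index)) {
    N <- (1 + sqrt(1 + 8 * ncol(features))) / 2
    if (abs(N - round(N)) > 1e-9)
      stop("feature count ", ncol(features), " is not N(N-1)/2 for integer N")
    pair_index <- region_pair_index(round(N))
  }
  stopifnot(nrow(pair_index) == ncol(features))
  if (is.null(colnames(features)))
    colnames(features) <- paste0("fc_", pair_index$i, "_", pair_index$j)
  if (is.null(subjects)) subjects <- seq_len(n)
  if (!is.null(age)) stopifnot(length(age) == n)
  if (!is.null(sex)) {
    sex <- as.integer(sex)
    stopifnot(length(sex) == n, all(sex %in% c(0L, 1L)))
  }
  structure(list(subjects = subjects, features = features, group = group,
                 age = age, sex = sex, pair_index = pair_index,
                 N = max(pair_index$j)),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d subjects x %d FC features (%d regions); groups %d/%d\n",
              nrow(x$features), ncol(x$features), x$N,
              sum(x$group == 0), sum(x$group == 1)))
  invisible(x)
}

#' Write / read a feature table as CSV
#'
#' Columns: subject, group, age, sex, then the `fc_i_j` pair columns.
#'
#' @param ft a [feature_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(ft, path) {
  df <- data.frame(subject = ft$subjects, group = ft$group,
                   age = if (is.null(ft$age)) NA else ft$age,
                   sex = if (is.null(ft$sex)) NA else ft$sex)
  utils::write.csv(cbind(df, as.data.frame(ft$features)), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  df <- utils::read.csv(path)
  fc_cols <- grep("^fc_", names(df))
  feature_table(as.matrix(df[, fc_cols, drop = FALSE]), group = df$group,
                age = if (all(is.na(df$age))) NULL else df$age,
                sex = if (all(is.na(df$sex))) NULL else df$sex,
                subjects = df$subject)
}

# Confound p-values on a subset of subjects (rows).
confound_pvalues <- function(features, age, sex, rows = seq_len(nrow(features))) {
  f <- features[rows, , drop = FALSE]
  M <- ncol(f)
  p_age <- rep(NA_real_, M)
  p_sex <- rep(NA_real_, M)
  degenerate <- logical(M)
  for (m in seq_len(M)) {
    x <- f[, m]
    if (stats::var(x) <= 0) { degenerate[m] <- TRUE; next }
    if (!is.null(age))
      p_age[m] <- stats::cor.test(x, age[rows])$p.value
    if (!is.null(sex)) {
      g0 <- x[sex[rows] == 0]; g1 <- x[sex[rows] == 1]
      if (length(g0) > 1 && length(g1) > 1 &&
          (stats::var(g0) > 0 || stats::var(g1) > 0))
        p_sex[m] <- stats::t.test(g0, g1)$p.value
      else degenerate[m] <- TRUE
    }
  }
  list(p_age = p_age, p_sex = p_sex, degenerate = degenerate)
}

#' Exclude FC features associated with age or sex
#'
#' A feature is excluded when its Pearson correlation with age, or a Welch
#' two-sample t test between the sexes, is significant at `alpha`. Constant
#' (degenerate) features are excluded and flagged. With no covariates
#' available the filter is vacuous (all kept, with a warning).
#'
#' @param ft a [feature_table()].
#' @param alpha significance threshold, default 0.05.
#' @return list with `keep` (logical per feature), `p_age`, `p_sex`,
#'   `degenerate`, `n_excluded`.
#' @export
confound_filter <- function(ft, alpha = 0.05) {
  stopifnot(inherits(ft, "feature_table"))
  M <- ncol(ft$features)
  if (is.null(ft$age) && is.null(ft$sex)) {
    warning("no age/sex covariates; confound filter is vacuous")
    return(list(keep = rep(TRUE, M), p_age = rep(NA_real_, M),
                p_sex = rep(NA_real_, M), degenerate = logical(M),
                n_excluded = 0L))
  }
  pv <- confound_pvalues(ft$features, ft$age, ft$sex)
  keep <- !pv$degenerate &
    (is.na(pv$p_age) | pv$p_age >= alpha) &
    (is.na(pv$p_sex) | pv$p_sex >= alpha)
  list(keep = keep, p_age = pv$p_age, p_sex = pv$p_sex,
       degenerate = pv$degenerate, n_excluded = sum(!keep))
}

# Stratified fold assignment, seeded.
stratified_folds <- function(group, folds, seed) {
  fold <- integer(length(group))
  with_seed(seed, {
    for (g in unique(group)) {
      idx <- which(group == g)
      if (length(idx) < folds)
        stop("class ", g, " has fewer subjects (", length(idx),
             ") than folds (", folds, ")")
      fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  fold
}

#' L2-regularized logistic regression with stratified cross-validation
#'
#' Per fold: features are z-scored with training-fold statistics, an
#' L2 (ridge) logistic regression is fit on the training subjects, and
#' accuracy (0.5 threshold) and ROC AUC are evaluated on the held-out fold.
#' The confound filter can be applied on the whole sample before CV
#' (replicating the common practice, at some leakage risk) or recomputed
#' within each training fold (default).
#'
#' @param ft a [feature_table()].
#' @param folds number of folds, default 5.
#' @param c_reg inverse regularization strength C (ridge penalty is
#'   1/(C n)); default 1.
#' @param seed RNG seed for fold assignment.
#' @param filter_scope `"within_fold"` (default), `"whole_sample"`, or
#'   `"none"`.
#' @param alpha confound-filter significance threshold.
#' @return An object of class `cv_result`: `per_fold` (accuracy, auc),
#'   `mean_accuracy`, `sd_accuracy`, `mean_auc`, `sd_auc`, `coefficients`
#'   (folds x M, zero for filtered-out features), `keep` (features kept per
#'   fold, logical folds x M), `pair_index`.
#' @export
fit_classifier_cv <- function(ft, folds = 5, c_reg = 1, seed = 1,
                              filter_scope = c("within_fold", "whole_sample", "none"),
                              alpha = 0.05) {
  stopifnot(inherits(ft, "feature_table"))
  filter_scope <- match.arg(filter_scope)
  y <- ft$group
  if (length(unique(y)) < 2L) stop("both classes must be present")
  X <- ft$features
  M <- ncol(X)
  fold <- stratified_folds(y, folds, seed)
  keep_global <- rep(TRUE, M)
  if (filter_scope == "whole_sample")
    keep_global <- confound_filter(ft, alpha)$keep
  per_fold <- data.frame(fold = seq_len(folds), accuracy = NA_real_, auc = NA_real_)
  coefs <- matrix(0, folds, M, dimnames = list(NULL, colnames(X)))
  keep_mat <- matrix(FALSE, folds, M)
  for (f in seq_len(folds)) {
    tr <- which(fold != f); te <- which(fold == f)
    if (length(unique(y[te])) < 2L || length(unique(y[tr])) < 2L)
      stop("fold ", f, " has a single class; reduce folds or rebalance")
    keep <- keep_global
    if (filter_scope == "within_fold" && !(is.null(ft$age) && is.null(ft$sex))) {
      pv <- confound_pvalues(X, ft$age, ft$sex, rows = tr)
      keep <- !pv$degenerate &
        (is.na(pv$p_age) | pv$p_age >= alpha) &
        (is.na(pv$p_sex) | pv$p_sex >= alpha)
    }
    if (!any(keep)) stop("confound filter removed every feature in fold ", f)
    keep_mat[f, ] <- keep
    mu <- colMeans(X[tr, keep, drop = FALSE])
    sd <- apply(X[tr, keep, drop = FALSE], 2, stats::sd)
    sd[sd <= 0] <- 1
    Ztr <- sweep(sweep(X[tr, keep, drop = FALSE], 2, mu), 2, sd, `/`)
    Zte <- sweep(sweep(X[te, keep, drop = FALSE], 2, mu), 2, sd, `/`)
    lambda <- 1 / (c_reg * length(tr))
    fit <- glmnet::glmnet(Ztr, factor(y[tr], levels = c(0, 1)),
                          family = "binomial", alpha = 0, lambda = lambda,
                          standardize = FALSE, thresh = 1e-10)
    prob <- as.numeric(stats::predict(fit, Zte, type = "response"))
    per_fold$accuracy[f] <- mean((prob > 0.5) == (y[te] == 1))
    per_fold$auc[f] <- as.numeric(pROC::auc(pROC::roc(
      response = y[te], predictor = prob, levels = c(0, 1),
      direction = "<", quiet = TRUE)))
    coefs[f, keep] <- as.numeric(stats::coef(fit))[-1]
  }
  structure(list(per_fold = per_fold,
                 mean_accuracy = mean(per_fold$accuracy),
                 sd_accuracy = stats::sd(per_fold$accuracy),
                 mean_auc = mean(per_fold$auc),
                 sd_auc = stats::sd(per_fold$auc),
                 coefficients = coefs, keep = keep_mat,
                 pair_index = ft$pair_index, folds = folds),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d-fold CV: accuracy %.3f +/- %.3f, AUC %.3f +/- %.3f\n",
              x$folds, x$mean_accuracy, x$sd_accuracy, x$mean_auc, x$sd_auc))
  invisible(x)
}

#' Region importance from cross-validated coefficients
#'
#' Coefficients are aggregated across folds as the mean absolute value,
#' scaled by the maximum (`w' = |w| / max|w|`); a region's importance is
#' the mean of `w'` over its N-1 incident pairs, and the final score is
#' renormalized so the most important region equals 1.
#'
#' @param cv a `cv_result` (or a numeric coefficient vector).
#' @param pair_index a [region_pair_index()]; taken from `cv` when missing.
#' @return An object of class `importance_map`: `importance` (per-region,
#'   max 1), `raw_importance`, `pair_weights` (`w'` per pair), `N`.
#' @export
region_importance <- function(cv, pair_index = NULL) {
  if (inherits(cv, "cv_result")) {
    if (is.null(pair_index)) pair_index <- cv$pair_index
    w <- colMeans(abs(cv$coefficients))
  } else {
    w <- abs(as.numeric(cv))
  }
  stopifnot(!is.null(pair_index), length(w) == nrow(pair_index))
  if (max(w) == 0) stop("all coefficients are zero; importance undefined")
  wp <- w / max(w)
  N <- max(pair_index$j)
  imp <- vapply(seq_len(N), function(i) {
    inc <- pair_index$i == i | pair_index$j == i
    sum(wp[inc]) / (N - 1)
  }, numeric(1))
  structure(list(importance = imp / max(imp), raw_importance = imp,
                 pair_weights = wp, N = N),
            class = "importance_map")
}

#' @export
print.importance_map <- function(x, ...) {
  cat(sprintf("<importance_map> %d regions; top: %s\n", x$N,
              paste(utils::head(order(-x$importance), 5), collapse = ", ")))
  invisible(x)
}

#' Write region importance onto a partition as a NIfTI map
#'
#' Every voxel of region i is set to its normalized importance.
#'
#' @param imp an `importance_map`.
#' @param p the `partition` whose regions the importance refers to.
#' @param path output NIfTI path.
#' @return `path`, invisibly.
#' @export
write_importance_nifti <- function(imp, p, path) {
  stopifnot(imp$N == p$K)
  mask <- p$mask
  arr <- array(0, dim = mask$geometry$dims)
  arr[mask$linear] <- imp$importance[p$labels]
  img <- RNifti::asNifti(arr)
  img <- RNifti::`sform<-`(img, structure(mask$geometry$affine, code = 2L))
  RNifti::pixdim(img) <- mask$geometry$voxel_size
  RNifti::writeNifti(img, path)
  invisible(path)
}
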