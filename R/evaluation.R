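#' Dice agreement of two partitions via their co-cluster matrices
#'
#' \eqn{D = 2\sum_{ij} x_{ij} y_{ij} / (\sum_{ij} x_{ij} + \sum_{ij} y_{ij})}
#' over the zero-diagonal binary co-cluster (AR) matrices: twice the number
#' of voxel pairs co-clustered in both, over the total co-clustered pairs in
#' each. Invariant to label permutation; in `[0, 1]`.
#'
#' @param x,y `ar_matrix` objects (or `partition`s / label vectors, coerced
#'   via [to_adjacency()]) of the same size.
#' @return Dice coefficient; `NaN` with a warning when both partitions are
#'   all-singletons (no co-clustered pair on either side).
#' @export
dice_ar <- function(x, y) {
  if (!inherits(x, "ar_matrix")) x <- to_adjacency(x)
  if (!inherits(y, "ar_matrix")) y <- to_adjacency(y)
  if (x$n != y$n) stop("AR matrices have different sizes")
  denom <- sum(x$mat) + sum(y$mat)
  if (denom == 0) {
    warning("both partitions are all-singletons; AR-Dice undefined")
    return(NaN)
  }
  2 * sum(x$mat * y$mat) / denom
}

#' Normalized mutual information between two labelings
#'
#' \eqn{NMI = 2 I(X,Y) / (H(X) + H(Y))} from the empirical joint label
#' distribution (natural log; the base cancels). Conventions: terms with
#' zero probability contribute 0; if both labelings are single-cluster
#' (both entropies 0) the labelings are identical and NMI is 1; if exactly
#' one is single-cluster, I = 0 and NMI is 0.
#'
#' @param x,y label vectors (or `partition`s) of equal length.
#' @return NMI in `[0, 1]`.
#' @export
nmi <- function(x, y) {
  if (inherits(x, "partition")) x <- x$labels
  if (inherits(y, "partition")) y <- y$labels
  stopifnot(length(x) == length(y), length(x) >= 1)
  tab <- table(x, y)
  n <- sum(tab)
  pxy <- tab / n
  px <- rowSums(pxy)
  py <- colSums(pxy)
  hx <- -sum(px[px > 0] * log(px[px > 0]))
  hy <- -sum(py[py > 0] * log(py[py > 0]))
  if (hx + hy == 0) return(1)
  pos <- pxy > 0
  mi <- sum(pxy[pos] * log(pxy[pos] / outer(px, py)[pos]))
  val <- 2 * mi / (hx + hy)
  min(max(val, 0), 1)
}

#' Intraregional homogeneity of a partition
#'
#' IRH of a cluster is the mean Pearson correlation over all unordered
#' voxel pairs within it; AIRH is the cluster-size-weighted average of IRH
#' over the mask. Singleton clusters have no pairs: they are excluded and
#' counted, and the AIRH weights are renormalized over the included
#' clusters.
#'
#' @param ts a `timeseries_matrix` on the partition's mask.
#' @param p a `partition`.
#' @return An object of class `homogeneity_report`: `per_cluster` (data
#'   frame label / size / irh), `airh`, `excluded_singletons`.
#' @export
irh <- function(ts, p) {
  stopifnot(inherits(ts, "timeseries_matrix"), inherits(p, "partition"))
  if (!identical(ts$mask$linear, p$mask$linear))
    stop("time series and partition are on different masks")
  if (length(ts$zero_variance) > 0)
    stop("zero-variance voxel(s) in the mask (e.g. row ", ts$zero_variance[1],
         "); correlations undefined — drop them first")
  sizes <- tabulate(p$labels, p$K)
  irh_k <- rep(NA_real_, p$K)
  for (k in seq_len(p$K)) {
    mem <- which(p$labels == k)
    if (length(mem) < 2L) next
    R <- stats::cor(t(ts$values[mem, , drop = FALSE]))
    irh_k[k] <- mean(R[upper.tri(R)])
  }
  included <- which(!is.na(irh_k))
  if (length(included) == 0L) stop("all clusters are singletons; IRH undefined")
  w <- sizes[included] / sum(sizes[included])
  structure(list(per_cluster = data.frame(label = seq_len(p$K), size = sizes,
                                          irh = irh_k),
                 airh = sum(w * irh_k[included]),
                 excluded_singletons = sum(sizes == 1L)),
            class = "homogeneity_report")
}

#' @export
print.homogeneity_report <- function(x, ...) {
  cat(sprintf("<homogeneity_report> AIRH = %.4f over %d clusters (%d singletons excluded)\n",
              x$airh, nrow(x$per_cluster), x$excluded_singletons))
  invisible(x)
}

#' Size-weighted average intraregional homogeneity
#'
#' Convenience accessor: the AIRH value of [irh()].
#'
#' @inheritParams irh
#' @return AIRH in `[-1, 1]`.
#' @export
airh <- function(ts, p) irh(ts, p)$airh

#' Winner-take-all matching of a partition to a template
#'
#' Relabels every cluster of `p` to the template label covering the most of
#' its voxels (ties toward the lowest template label). Template label 0
#' denotes uncovered voxels: a cluster wholly outside template coverage is
#' assigned 0 and flagged.
#'
#' @param p a `partition`.
#' @param template a `partition`-like object on the same mask, or an integer
#'   label vector (0 allowed for uncovered voxels).
#' @return An object of class `match_result`: `relabeled` (integer vector in
#'   template label space), `mapping` (per-cluster assigned template label),
#'   `overlap` (K x template-label count matrix), `template_dice`
#'   (per-template-label spatial Dice between the template region and the
#'   union of clusters mapped to it), `unmatched` (clusters assigned 0).
#' @export
winner_take_all_match <- function(p, template) {
  tl <- if (inherits(template, "partition")) template$labels else as.integer(template)
  stopifnot(length(tl) == length(p$labels))
  tvals <- sort(unique(tl))
  overlap <- table(factor(p$labels, levels = seq_len(p$K)),
                   factor(tl, levels = tvals))
  overlap <- unclass(overlap)
  mapping <- integer(p$K)
  pos <- tvals[tvals > 0]
  for (k in seq_len(p$K)) {
    row <- overlap[k, as.character(pos), drop = TRUE]
    if (length(pos) == 0L || max(row) == 0) {
      mapping[k] <- 0L
    } else {
      mapping[k] <- pos[which.max(row)]  # which.max takes the first (lowest) on ties
    }
  }
  relabeled <- mapping[p$labels]
  template_dice <- vapply(pos, function(t) {
    a <- tl == t
    b <- relabeled == t
    if (sum(a) + sum(b) == 0) return(NaN)
    2 * sum(a & b) / (sum(a) + sum(b))
  }, numeric(1))
  names(template_dice) <- pos
  structure(list(relabeled = relabeled, mapping = mapping, overlap = overlap,
                 template_dice = template_dice,
                 unmatched = which(mapping == 0L)),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> %d clusters -> %d template labels; mean per-label Dice %.3f\n",
              nrow(x$overlap), ncol(x$overlap), mean(x$template_dice, na.rm = TRUE)))
  invisible(x)
}

#' Reproducibility of a group partition against validation subjects
#'
#' The validation protocol: NMI and AR-Dice between the group partition and
#' each validation subject's individual partition.
#'
#' @param group a `partition` (group level).
#' @param subjects list of `partition`s (validation set).
#' @return data frame with one row per subject: `subject`, `nmi`, `dice`.
#' @export
reproducibility <- function(group, subjects) {
  ar_g <- to_adjacency(group)
  do.call(rbind, lapply(seq_along(subjects), function(i) {
    data.frame(subject = i,
               nmi = nmi(group, subjects[[i]]),
               dice = dice_ar(ar_g, to_adjacency(subjects[[i]])))
  }))
}

#' Tidy export of metric values
#'
#' @param df data frame of metric rows (`metric`, `K`, `transform`,
#'   `subject`, `value`); written as CSV.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
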