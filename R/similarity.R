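#' Order-preserving transform specification
#'
#' The similarity measure reshapes positive FC values with a strictly
#' monotone map \eqn{f} on \eqn{[0,1]} satisfying \eqn{f(0)=0} and
#' \eqn{f(1)=1}, so ranks are preserved while the value distribution is
#' expanded or compressed. Available families:
#' \describe{
#'   \item{origin}{identity, \eqn{f(x)=x} — the untransformed reference.}
#'   \item{root}{\eqn{f(x)=(k+1)x/(1+kx)} — widens low/medium differences.}
#'   \item{square}{\eqn{f(x)=x^a} — widens medium/high differences.}
#'   \item{gaussian}{\eqn{f(x)=(e^{-(x-1)^2/2\sigma^2}-e^{-1/2\sigma^2})
#'     /(1-e^{-1/2\sigma^2})} — smooths the distribution.}
#' }
#'
#' @param name one of `"origin"`, `"root"`, `"square"`, `"gaussian"`.
#' @param param positive hyperparameter: `k` for root (default 1), `a` for
#'   square (default 2), `sigma` for gaussian (default 1); ignored for origin.
#' @return An object of class `transform_spec`.
#' @export
transform_spec <- function(name = c("origin", "root", "square", "gaussian"),
                           param = NULL) {
  name <- match.arg(name)
  if (is.null(param))
    param <- switch(name, origin = NA_real_, root = 1, square = 2, gaussian = 1)
  if (name != "origin" && (!is.finite(param) || param <= 0))
    stop("transform parameter must be > 0")
  structure(list(name = name, param = as.numeric(param)), class = "transform_spec")
}

#' @export
print.transform_spec <- function(x, ...) {
  cat(sprintf("<transform_spec> %s%s\n", x$name,
              if (x$name == "origin") "" else sprintf(" (param = %g)", x$param)))
  invisible(x)
}

#' Evaluate an order-preserving transform
#'
#' @param x numeric vector with values in `[0, 1]`.
#' @param spec a [transform_spec()].
#' @return `f(x)`, same length as `x`.
#' @export
fc_transform <- function(x, spec) {
  stopifnot(inherits(spec, "transform_spec"))
  if (any(x < 0 | x > 1, na.rm = TRUE))
    stop("transform domain error: values outside [0, 1]")
  p <- spec$param
  switch(spec$name,
    origin   = x,
    root     = (p + 1) * x / (1 + p * x),
    square   = x^p,
    gaussian = (exp(-(x - 1)^2 / (2 * p^2)) - exp(-1 / (2 * p^2))) /
               (1 - exp(-1 / (2 * p^2))))
}

#' Numerically validate the transform axioms
#'
#' Checks, on a uniform grid over `[0,1]`, that a transform satisfies the
#' required constraints: `f(0) = 0`, `f(1) = 1`, strict monotonicity, and
#' range within `[0, 1]`.
#'
#' @param spec a [transform_spec()] (or any function of one argument).
#' @param grid_size number of grid points, >= 3.
#' @param tol numeric tolerance on the boundary conditions.
#' @return list with logical fields `f0`, `f1`, `monotone`, `range`, `pass`.
#' @export
validate_transform <- function(spec, grid_size = 1000, tol = 1e-12) {
  stopifnot(grid_size >= 3)
  f <- if (is.function(spec)) spec else function(x) fc_transform(x, spec)
  x <- seq(0, 1, length.out = grid_size)
  y <- f(x)
  out <- list(f0 = abs(y[1]) <= tol,
              f1 = abs(y[grid_size] - 1) <= tol,
              monotone = all(diff(y) > 0),
              range = all(y >= -tol & y <= 1 + tol))
  out$pass <- all(unlist(out))
  out
}

#' 26-neighbourhood graph of a voxel mask
#'
#' Two in-mask voxels are adjacent when their grid offsets lie in
#' \{-1,0,1\}^3 (excluding the zero offset), i.e. they share a face, edge or
#' corner — up to 26 neighbours per voxel. A larger `radius` (Euclidean, in
#' voxel units) may be given for sensitivity analyses.
#'
#' @param mask a [voxel_mask()].
#' @param radius neighbourhood radius in voxel units; default `sqrt(3)`
#'   yields the 26-neighbourhood.
#' @return An object of class `neighbor_graph`: `mask`, `edges` (m x 2
#'   integer matrix, i < j, in-mask indices), `adjacency` (list of integer
#'   neighbour vectors), `isolated` (in-mask indices with no neighbours).
#' @export
build_neighbor_graph <- function(mask, radius = sqrt(3)) {
  stopifnot(inherits(mask, "voxel_mask"))
  dims <- mask$geometry$dims
  r <- max(1L, as.integer(floor(radius)))
  offs <- as.matrix(expand.grid(dx = -r:r, dy = -r:r, dz = -r:r))
  keep <- rowSums(offs^2) > 0 & rowSums(offs^2) <= radius^2 + 1e-9
  offs <- offs[keep, , drop = FALSE]
  # only half the offsets: each undirected edge found once (i < j by linear order)
  half <- offs[offs[, 3] > 0 |
               (offs[, 3] == 0 & (offs[, 2] > 0 | (offs[, 2] == 0 & offs[, 1] > 0))),
               , drop = FALSE]
  lut <- mask_index_lut(mask)
  co <- mask$coords
  ei <- ej <- vector("list", nrow(half))
  for (k in seq_len(nrow(half))) {
    nb <- co + matrix(half[k, ], nrow = mask$n, ncol = 3, byrow = TRUE)
    ok <- nb[, 1] >= 1L & nb[, 1] <= dims[1] &
          nb[, 2] >= 1L & nb[, 2] <= dims[2] &
          nb[, 3] >= 1L & nb[, 3] <= dims[3]
    lin <- (nb[ok, 3] - 1L) * (dims[1] * dims[2]) + (nb[ok, 2] - 1L) * dims[1] + nb[ok, 1]
    tgt <- lut[lin]
    hit <- tgt > 0L
    ei[[k]] <- which(ok)[hit]
    ej[[k]] <- tgt[hit]
  }
  i <- unlist(ei); j <- unlist(ej)
  sw <- i > j
  edges <- cbind(ifelse(sw, j, i), ifelse(sw, i, j))
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  storage.mode(edges) <- "integer"
  adjacency <- rep(list(integer(0)), mask$n)
  if (nrow(edges) > 0) {
    nb_of <- split(c(edges[, 2], edges[, 1]), c(edges[, 1], edges[, 2]))
    idx <- as.integer(names(nb_of))
    adjacency[idx] <- lapply(nb_of, function(v) sort(as.integer(v)))
  }
  isolated <- which(lengths(adjacency) == 0L)
  structure(list(mask = mask, edges = edges, adjacency = adjacency,
                 isolated = isolated, radius = radius),
            class = "neighbor_graph")
}

#' @export
print.neighbor_graph <- function(x, ...) {
  cat(sprintf("<neighbor_graph> %d voxels, %d edges, %d isolated\n",
              x$mask$n, nrow(x$edges), length(x$isolated)))
  invisible(x)
}

new_sparse_similarity <- function(mat, mask, transform = NULL) {
  mat <- methods::as(methods::as(Matrix::forceSymmetric(mat, uplo = "U"),
                                 "generalMatrix"), "CsparseMatrix")
  mat <- Matrix::drop0(mat)
  structure(list(n = nrow(mat), mat = mat, mask = mask, transform = transform),
            class = "sparse_similarity")
}

#' @export
print.sparse_similarity <- function(x, ...) {
  cat(sprintf("<sparse_similarity> %d voxels, %d stored entries%s\n",
              x$n, Matrix::nnzero(x$mat),
              if (is.null(x$transform)) " (untransformed)"
              else paste0(" (", x$transform$name, ")")))
  invisible(x)
}

#' Spatially constrain an FC matrix to positive neighbour correlations
#'
#' Keeps an FC value only when the two voxels are 26-neighbours *and* the
#' correlation is positive; everything else (negative, zero, or spatially
#' remote correlations) is absent, i.e. treated as similarity 0. This gate
#' is what makes the resulting clusters spatially contiguous.
#'
#' @param fc an `fc_matrix` from [pearson_fc()].
#' @param graph a [build_neighbor_graph()] on the same mask.
#' @return A `sparse_similarity` with raw (untransformed) values in `(0, 1]`.
#' @export
spatial_constrain <- function(fc, graph) {
  stopifnot(inherits(fc, "fc_matrix"), inherits(graph, "neighbor_graph"))
  if (!identical(fc$mask$linear, graph$mask$linear))
    stop("fc and neighbor graph are on different masks")
  e <- graph$edges
  vals <- fc$values[e]
  keep <- vals > 0
  mat <- Matrix::sparseMatrix(i = e[keep, 1], j = e[keep, 2], x = vals[keep],
                              dims = c(fc$mask$n, fc$mask$n), symmetric = TRUE)
  new_sparse_similarity(mat, fc$mask, transform = NULL)
}

#' Apply an order-preserving transform to a sparse similarity
#'
#' Transforms every stored entry; since any admissible `f` has `f(0) = 0`
#' and `f(x) > 0` for `x > 0`, absent entries stay absent and the sparsity
#' pattern is unchanged.
#'
#' @param s a `sparse_similarity` with values in `(0, 1]`.
#' @param spec a [transform_spec()].
#' @return A `sparse_similarity` with transformed values.
#' @export
apply_transform <- function(s, spec) {
  stopifnot(inherits(s, "sparse_similarity"), inherits(spec, "transform_spec"))
  mat <- s$mat
  mat@x <- fc_transform(mat@x, spec)
  new_sparse_similarity(mat, s$mask, transform = spec)
}

#' Write / read a sparse similarity as 3-column TSV with a JSON header
#'
#' Columns `i`, `j`, `value` with `i < j`, 0-based in-mask indices. The JSON
#' sidecar records the mask checksum and transform spec.
#'
#' @param s a `sparse_similarity`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_similarity_tsv <- function(s, path) {
  tri <- Matrix::triu(s$mat, k = 1)
  tm <- Matrix::summary(methods::as(tri, "TsparseMatrix"))
  ord <- order(tm$i, tm$j)
  utils::write.table(data.frame(i = tm$i[ord] - 1L, j = tm$j[ord] - 1L,
                                value = tm$x[ord]),
                     path, sep = "\t", row.names = FALSE, col.names = TRUE)
  meta <- list(n = s$n, mask_checksum = sum(s$mask$linear),
               transform = if (is.null(s$transform)) NULL
                           else list(name = s$transform$name, param = s$transform$param))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_similarity_tsv
#' @param mask the [voxel_mask()] the similarity was computed on.
#' @export
read_similarity_tsv <- function(path, mask) {
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  mat <- Matrix::sparseMatrix(i = df$i + 1L, j = df$j + 1L, x = df$value,
                              dims = c(mask$n, mask$n), symmetric = TRUE)
  transform <- NULL
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$mask_checksum) && meta$mask_checksum != sum(mask$linear))
      warning("similarity sidecar mask checksum does not match the supplied mask")
    if (!is.null(meta$transform))
      transform <- transform_spec(meta$transform$name, meta$transform$param)
  }
  new_sparse_similarity(mat, mask, transform = transform)
}

#' Full similarity pipeline for one subject
#'
#' Convenience composition: time-series extraction, Pearson FC, spatial
#' constraint, transform.
#'
#' @param volume 4D array or [read_volume_nifti()] result.
#' @param mask a [voxel_mask()].
#' @param spec a [transform_spec()] (default `origin`).
#' @param graph optional precomputed [build_neighbor_graph()].
#' @return A `sparse_similarity`.
#' @export
build_similarity <- function(volume, mask, spec = transform_spec("origin"),
                             graph = NULL) {
  ts <- extract_timeseries(volume, mask)
  fc <- pearson_fc(ts)
  if (is.null(graph) || !identical(graph$mask$linear, fc$mask$linear))
    graph <- build_neighbor_graph(fc$mask)
  apply_transform(spatial_constrain(fc, graph), spec)
}
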