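#' Extract in-mask voxel time series from a 4D volume
#'
#' Pulls the time course of every in-mask voxel, in mask enumeration order
#' (x fastest), into an n x T matrix. Voxels with zero temporal variance are
#' flagged (preprocessed data can contain flat voxels at mask edges); they
#' are kept here and handled by [pearson_fc()].
#'
#' @param volume 4D array, or the list returned by [read_volume_nifti()].
#' @param mask a [voxel_mask()] with the same spatial dimensions.
#' @param tr repetition time in seconds (metadata only).
#' @return An object of class `timeseries_matrix`: `values` (n x T), `mask`,
#'   `tr`, `zero_variance` (integer row indices).
#' @export
extract_timeseries <- function(volume, mask, tr = 1) {
  if (is.list(volume) && !is.null(volume$data)) {
    if (!is.null(volume$geometry))
      check_affines(volume$geometry$affine, mask$geometry$affine)
    if (!is.null(volume$tr) && is.finite(volume$tr) && volume$tr > 0)
      tr <- volume$tr
    volume <- volume$data
  }
  d <- dim(volume)
  if (length(d) != 4L) stop("`volume` must be a 4D array")
  if (!identical(as.integer(d[1:3]), mask$geometry$dims))
    stop("volume spatial dimensions (", paste(d[1:3], collapse = "x"),
         ") do not match mask dims (", paste(mask$geometry$dims, collapse = "x"), ")")
  if (d[4] < 3L) stop("need at least 3 time points, got ", d[4])
  nvox <- prod(d[1:3])
  dim(volume) <- c(nvox, d[4])
  values <- volume[mask$linear, , drop = FALSE]
  v <- rowvar(values)
  structure(list(values = values, mask = mask, tr = tr,
                 zero_variance = which(v <= 0 | !is.finite(v))),
            class = "timeseries_matrix")
}

rowvar <- function(m) {
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (ncol(m) - 1)
}

new_timeseries <- function(values, mask, tr = 1) {
  stopifnot(nrow(values) == mask$n, ncol(values) >= 3L)
  v <- rowvar(values)
  structure(list(values = values, mask = mask, tr = tr,
                 zero_variance = which(v <= 0 | !is.finite(v))),
            class = "timeseries_matrix")
}

#' @export
print.timeseries_matrix <- function(x, ...) {
  cat(sprintf("<timeseries_matrix> %d voxels x %d time points (TR %.3g s); %d zero-variance\n",
              nrow(x$values), ncol(x$values), x$tr, length(x$zero_variance)))
  invisible(x)
}

#' Voxel-wise Pearson functional connectivity matrix
#'
#' Pearson correlation between the time series of every voxel pair,
#' the standard functional-connectivity (FC) measure. Zero-variance voxels
#' have no defined correlation: by default they are dropped from the matrix
#' and the mask (with a message); in strict mode they are an error.
#'
#' @param ts a `timeseries_matrix` from [extract_timeseries()].
#' @param drop_zero_variance drop flagged voxels (default) instead of erroring.
#' @return An object of class `fc_matrix`: `values` (n x n, symmetric, unit
#'   diagonal, entries in `[-1, 1]`), `mask` (possibly reduced), `n_dropped`.
#' @export
pearson_fc <- function(ts, drop_zero_variance = TRUE) {
  stopifnot(inherits(ts, "timeseries_matrix"))
  values <- ts$values
  mask <- ts$mask
  zv <- ts$zero_variance
  if (length(zv) > 0L) {
    if (!drop_zero_variance)
      stop("correlation undefined: ", length(zv),
           " zero-variance voxel(s), e.g. row ", zv[1])
    message("pearson_fc: dropping ", length(zv), " zero-variance voxel(s)")
    keep <- setdiff(seq_len(nrow(values)), zv)
    values <- values[keep, , drop = FALSE]
    inside <- mask$inside
    inside[mask$linear[zv]] <- FALSE
    mask <- voxel_mask(inside, mask$geometry)
  }
  fc <- stats::cor(t(values))
  fc[fc > 1] <- 1
  fc[fc < -1] <- -1
  diag(fc) <- 1
  structure(list(values = fc, mask = mask, n_dropped = length(zv)),
            class = "fc_matrix")
}

#' @export
print.fc_matrix <- function(x, ...) {
  cat(sprintf("<fc_matrix> %d x %d voxel correlations\n", nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Write / read an FC matrix as header-less TSV with a JSON sidecar
#'
#' The TSV holds the n x n values, one row per line; the sidecar (same path
#' with `.json` appended) records the mask provenance (dims, voxel size,
#' voxel count, linear indices checksum).
#'
#' @param fc an `fc_matrix`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_fc_tsv <- function(fc, path) {
  utils::write.table(fc$values, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  meta <- list(n = nrow(fc$values),
               dims = fc$mask$geometry$dims,
               voxel_size = fc$mask$geometry$voxel_size,
               mask_checksum = sum(fc$mask$linear))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_fc_tsv
#' @param mask the [voxel_mask()] the matrix was computed on.
#' @export
read_fc_tsv <- function(path, mask) {
  values <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(values) <- NULL
  if (nrow(values) != mask$n)
    stop("FC matrix size ", nrow(values), " does not match mask size ", mask$n)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$mask_checksum) && meta$mask_checksum != sum(mask$linear))
      warning("FC sidecar mask checksum does not match the supplied mask")
  }
  structure(list(values = values, mask = mask, n_dropped = 0L),
            class = "fc_matrix")
}
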