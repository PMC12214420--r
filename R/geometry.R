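#' Volume geometry
#'
#' Spatial frame of a 3D grid: dimensions, voxel size in mm and a 4x4
#' voxel-to-world affine. The affine defaults to a diagonal scaling by the
#' voxel size (origin at voxel (1,1,1)).
#'
#' @param dims integer(3), grid dimensions (nx, ny, nz), all >= 1.
#' @param voxel_size numeric(3), voxel edge lengths in mm, all > 0.
#' @param affine 4x4 voxel-to-world matrix, or `NULL` for the default.
#' @return An object of class `volume_geometry`.
#' @export
volume_geometry <- function(dims, voxel_size = c(1, 1, 1), affine = NULL) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3L, all(dims >= 1L))
  voxel_size <- as.numeric(voxel_size)
  stopifnot(length(voxel_size) == 3L, all(voxel_size > 0))
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
  }
  stopifnot(is.matrix(affine), all(dim(affine) == c(4L, 4L)))
  structure(list(dims = dims, voxel_size = voxel_size, affine = affine),
            class = "volume_geometry")
}

#' Voxel mask over a 3D grid
#'
#' A binary mask plus a deterministic enumeration of its in-mask voxels.
#' Voxels are enumerated in grid storage order — x fastest, then y, then z —
#' so the enumeration is a stable bijection onto `1..n` and reproducible
#' across runs, which downstream co-cluster matrices rely on.
#'
#' @param inside logical (or 0/1 numeric) 3D array; `TRUE`/nonzero = in mask.
#' @param geometry a [volume_geometry()]; defaults to unit voxels of the
#'   array's dimensions.
#' @return An object of class `voxel_mask` with fields `geometry`, `inside`,
#'   `coords` (n x 3 integer matrix of 1-based grid coordinates in mask
#'   order), `linear` (grid linear indices) and `n`.
#' @export
voxel_mask <- function(inside, geometry = NULL) {
  if (!is.array(inside) || length(dim(inside)) != 3L)
    stop("`inside` must be a 3D array")
  inside <- array(as.logical(inside) & !is.na(inside), dim = dim(inside))
  if (is.null(geometry)) geometry <- volume_geometry(dim(inside))
  if (!identical(as.integer(dim(inside)), geometry$dims))
    stop("mask dimensions do not match geometry dims")
  linear <- which(inside)          # ascending = x fastest, then y, then z
  if (length(linear) < 2L)
    stop("degenerate mask: fewer than 2 in-mask voxels")
  coords <- arrayInd(linear, dim(inside))
  storage.mode(coords) <- "integer"
  structure(list(geometry = geometry, inside = inside, coords = coords,
                 linear = linear, n = length(linear)),
            class = "voxel_mask")
}

#' @export
print.voxel_mask <- function(x, ...) {
  cat(sprintf("<voxel_mask> %d voxels in a %s grid (voxel %s mm)\n",
              x$n, paste(x$geometry$dims, collapse = "x"),
              paste(format(x$geometry$voxel_size), collapse = "x")))
  invisible(x)
}

#' Coordinates of in-mask voxels in world units (mm)
#' @param mask a [voxel_mask()]
#' @return n x 3 numeric matrix.
#' @export
mask_coords_mm <- function(mask) {
  sweep(mask$coords, 2, mask$geometry$voxel_size, `*`)
}

# Lookup table: grid linear index -> in-mask row id (0 outside mask).
mask_index_lut <- function(mask) {
  lut <- integer(prod(mask$geometry$dims))
  lut[mask$linear] <- seq_len(mask$n)
  lut
}

geometry_from_nifti <- function(img) {
  hdr <- RNifti::niftiHeader(img)
  d <- dim(img)
  volume_geometry(d[1:3], voxel_size = abs(hdr$pixdim[2:4]),
                  affine = structure(RNifti::xform(img), dimnames = NULL))
}

#' Read a binary mask from a NIfTI-1 file
#'
#' Nonzero voxels are in-mask.
#'
#' @param path NIfTI file path.
#' @return A [voxel_mask()].
#' @export
read_mask_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) arr <- arr[, , , 1]
  voxel_mask(arr != 0, geometry_from_nifti(img))
}

#' Read a 4D fMRI volume from a NIfTI-1 file
#'
#' @param path NIfTI file path.
#' @return list with `data` (4D array) and `geometry` ([volume_geometry()]),
#'   plus `tr` (repetition time in seconds, if recorded).
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 4L) stop("expected a 4D volume: ", path)
  hdr <- RNifti::niftiHeader(img)
  list(data = arr, geometry = geometry_from_nifti(img),
       tr = unname(hdr$pixdim[5]))
}

# Warn when two affines disagree beyond tolerance.
check_affines <- function(a, b, tol = 1e-4) {
  if (max(abs(a - b)) > tol)
    warning("affines differ by more than ", tol, "; spatial frames may not match")
  invisible(NULL)
}

#' Write a partition as a NIfTI-1 integer label map
#'
#' Background voxels are 0, clusters 1..K.
#'
#' @param p a [partition] (see [spectral_partition()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_labels_nifti <- function(p, path) {
  mask <- p$mask
  arr <- array(0L, dim = mask$geometry$dims)
  arr[mask$linear] <- p$labels
  img <- RNifti::asNifti(arr)
  img <- RNifti::`sform<-`(img, structure(mask$geometry$affine, code = 2L))
  RNifti::pixdim(img) <- mask$geometry$voxel_size
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read an integer label map as a partition on a mask
#'
#' @param path NIfTI label-map path (0 = background).
#' @param mask [voxel_mask()] on which to interpret labels; by default the
#'   nonzero voxels of the label map itself.
#' @return A [partition].
#' @export
read_labels_nifti <- function(path, mask = NULL) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) arr <- arr[, , , 1]
  if (is.null(mask)) {
    mask <- voxel_mask(arr != 0, geometry_from_nifti(img))
  } else {
    check_affines(geometry_from_nifti(img)$affine, mask$geometry$affine)
  }
  labels <- as.integer(round(arr[mask$linear]))
  new_partition(labels, mask, validate = FALSE)
}

#' Write a 4D volume (and optional mask) to NIfTI-1
#'
#' @param data 4D array.
#' @param geometry a [volume_geometry()].
#' @param path output path.
#' @param tr repetition time, seconds.
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(data, geometry, path, tr = 1) {
  stopifnot(length(dim(data)) == 4L)
  img <- RNifti::asNifti(data)
  img <- RNifti::`sform<-`(img, structure(geometry$affine, code = 2L))
  RNifti::pixdim(img) <- c(geometry$voxel_size, tr)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a mask to NIfTI-1
#' @param mask a [voxel_mask()]
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask_nifti <- function(mask, path) {
  arr <- array(0L, dim = mask$geometry$dims)
  arr[mask$linear] <- 1L
  img <- RNifti::asNifti(arr)
  img <- RNifti::`sform<-`(img, structure(mask$geometry$affine, code = 2L))
  RNifti::pixdim(img) <- mask$geometry$voxel_size
  RNifti::writeNifti(img, path)
  invisible(path)
}

# Evaluate an expression with a locally seeded RNG, restoring global state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
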