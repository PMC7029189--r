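#' Volume grid geometry
#'
#' A `vol_grid` describes the geometry of a 3-D voxel grid: its shape
#' (voxels per axis), the 4x4 affine mapping 0-based voxel indices to world
#' coordinates in mm, and the voxel sizes (the column norms of the affine's
#' linear part). All model computations in this package operate in 0-based
#' voxel-index space; the affine is carried for I/O and for reporting in mm.
#'
#' @param shape integer vector of length 3, voxels per axis.
#' @param affine 4x4 numeric matrix mapping voxel indices to world mm.
#'   Defaults to the identity (1 mm isotropic voxels at the origin).
#' @return An object of class `vol_grid` with fields `shape`, `affine` and
#'   `voxel_sizes`.
#' @examples
#' vol_grid(c(9, 9, 9))
#' @export
vol_grid <- function(shape, affine = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L))
    stop("'shape' must be 3 positive integers")
  if (is.null(affine)) affine <- diag(4)
  affine <- unclass(affine)
  attributes(affine) <- list(dim = c(4L, 4L))
  if (!is.numeric(affine) || !all(dim(affine) == c(4L, 4L)))
    stop("'affine' must be a 4x4 numeric matrix")
  if (abs(det(affine)) < .Machine$double.eps)
    stop("'affine' must be invertible")
  vs <- sqrt(colSums(affine[1:3, 1:3, drop = FALSE]^2))
  structure(list(shape = shape, affine = affine, voxel_sizes = vs),
            class = "vol_grid")
}

#' @export
print.vol_grid <- function(x, ...) {
  cat(sprintf("<vol_grid> %s voxels, voxel sizes %s mm\n",
              paste(x$shape, collapse = " x "),
              paste(signif(x$voxel_sizes, 4), collapse = " x ")))
  invisible(x)
}

grids_match <- function(a, b, tol = 1e-4) {
  identical(a$shape, b$shape) && max(abs(a$affine - b$affine)) < tol
}

#' Read a 3-D or 4-D NIfTI volume
#'
#' Reads a NIfTI-1 file and returns the data array together with its grid
#' geometry. A trailing singleton fourth dimension is dropped, so 3-D masks
#' come back as 3-D arrays.
#'
#' @param path path to a readable NIfTI file.
#' @return A list with `data` (3-D or 4-D numeric array) and `grid`
#'   (a [vol_grid]).
#' @export
load_volume <- function(path) {
  if (!is.character(path) || length(path) != 1L)
    stop("'path' must be a single file path")
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e) stop("cannot read NIfTI file '", path,
                                           "': ", conditionMessage(e)))
  arr <- as.array(img)
  d <- dim(arr)
  if (length(d) < 3L || length(d) > 4L)
    stop("expected a 3-D or 4-D volume in '", path, "', got ",
         length(d), " dimensions")
  if (length(d) == 4L && d[4] == 1L) {
    arr <- array(arr, d[1:3])
    d <- d[1:3]
  }
  if (all(is.na(arr))) stop("volume '", path, "' contains only NaN/NA values")
  aff <- structure(as.numeric(RNifti::xform(img)), dim = c(4L, 4L))
  list(data = arr, grid = vol_grid(d[1:3], aff))
}

write_volume <- function(arr, grid, path) {
  img <- RNifti::asNifti(arr)
  nd <- length(dim(arr))
  RNifti::pixdim(img) <- c(grid$voxel_sizes, rep(1, max(0L, nd - 3L)))
  RNifti::`qform<-`(img, structure(grid$affine, code = 2L)) -> img
  RNifti::`sform<-`(img, structure(grid$affine, code = 2L)) -> img
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Define a region of interest from a mask
#'
#' Builds a `region_mask` from a binary (or logical) 3-D mask array. Voxels
#' are stored as 0-based integer index triplets in a fixed, reproducible
#' order: lexicographic with z slowest and x fastest (R's native array
#' order), so the row order of every downstream matrix is deterministic.
#'
#' @param mask 3-D array; nonzero/TRUE marks in-mask voxels.
#' @param grid the [vol_grid] the mask lives on.
#' @param label short text label for the region.
#' @return An object of class `region_mask` with fields `grid`,
#'   `voxel_indices` (n x 3 integer matrix, 0-based) and `label`.
#' @export
region_mask <- function(mask, grid, label = "region") {
  if (is.null(dim(mask)) || length(dim(mask)) != 3L)
    stop("'mask' must be a 3-D array")
  if (!identical(as.integer(dim(mask)), grid$shape))
    stop("mask shape does not match grid shape")
  keep <- which(mask != 0 & !is.na(mask))
  if (length(keep) == 0L) stop("mask '", label, "' is empty")
  ijk <- arrayInd(keep, dim(mask)) - 1L
  colnames(ijk) <- c("i", "j", "k")
  structure(list(grid = grid, voxel_indices = ijk, label = label),
            class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf("<region_mask> '%s': %d voxels on a %s grid\n", x$label,
              nrow(x$voxel_indices), paste(x$grid$shape, collapse = "x")))
  invisible(x)
}

n_voxels <- function(mask) nrow(mask$voxel_indices)

mask_linear_index <- function(mask) {
  s <- mask$grid$shape
  ijk <- mask$voxel_indices
  1L + ijk[, 1L] + s[1L] * (ijk[, 2L] + s[2L] * ijk[, 3L])
}

#' Extract a region's voxel time series
#'
#' Pulls the time courses of all in-mask voxels out of a 4-D data array,
#' one row per voxel in the mask's fixed voxel order.
#'
#' @param data4d 4-D numeric array (x, y, z, time).
#' @param grid the [vol_grid] of `data4d`.
#' @param mask a [region_mask] on the same grid (shape identical, affine
#'   equal within `tol`).
#' @param tol tolerance for the affine comparison.
#' @return An object of class `region_ts` with fields `mask`, `data`
#'   (n_voxels x n_timepoints matrix) and `demeaned` (FALSE).
#' @export
extract_region <- function(data4d, grid, mask, tol = 1e-4) {
  d <- dim(data4d)
  if (length(d) != 4L) stop("'data4d' must be a 4-D array")
  if (!grids_match(grid, mask$grid, tol))
    stop("mask grid does not match data grid (shape/affine mismatch)")
  if (!identical(as.integer(d[1:3]), grid$shape))
    stop("data shape does not match grid shape")
  flat <- matrix(data4d, nrow = prod(d[1:3]), ncol = d[4])
  dat <- flat[mask_linear_index(mask), , drop = FALSE]
  zero <- rowSums(abs(dat), na.rm = TRUE) == 0
  if (any(zero))
    warning(sum(zero), " voxel(s) in '", mask$label,
            "' have all-zero time series; retained")
  structure(list(mask = mask, data = dat, demeaned = FALSE),
            class = "region_ts")
}

#' @export
print.region_ts <- function(x, ...) {
  cat(sprintf("<region_ts> '%s': %d voxels x %d timepoints%s\n",
              x$mask$label, nrow(x$data), ncol(x$data),
              if (isTRUE(x$demeaned)) " (ROI mean removed)" else ""))
  invisible(x)
}

#' Remove the ROI-mean time course
#'
#' Subtracts the across-voxel mean time course of the region from every
#' voxel's time course, so correlations between regions are not driven by
#' the shared regional mean signal. Idempotent.
#'
#' @param ts a [region_ts] with at least 2 voxels.
#' @return The `region_ts` with `demeaned = TRUE`; the across-voxel mean of
#'   `data` is numerically zero at every time point.
#' @export
remove_region_mean <- function(ts) {
  stopifnot(inherits(ts, "region_ts"))
  if (nrow(ts$data) < 2L)
    stop("ROI-mean removal needs >= 2 voxels (it would annihilate a ",
         "single voxel's signal)")
  mu <- colMeans(ts$data, na.rm = TRUE)
  ts$data <- sweep(ts$data, 2L, mu, "-")
  ts$demeaned <- TRUE
  ts
}

#' Write a fitted-parameter map as NIfTI
#'
#' Paints one fitted connective field parameter into the seed region's
#' volume (NaN outside the seed mask) and writes it as a NIfTI file.
#'
#' @param cfm a [cf_fit] result (`cfmap`).
#' @param which parameter name: one of `"x0"`, `"y0"`, `"z0"`, `"sigma"`,
#'   `"fit_r2"`.
#' @param path output file path (`.nii` or `.nii.gz`).
#' @return The path, invisibly.
#' @export
write_parameter_map <- function(cfm, which, path) {
  stopifnot(inherits(cfm, "cfmap"))
  allowed <- c("x0", "y0", "z0", "sigma", "fit_r2")
  if (!is.character(which) || length(which) != 1L || !(which %in% allowed))
    stop("'which' must be one of: ", paste(allowed, collapse = ", "))
  if (nrow(cfm$fields) == 0L) stop("connective field map is empty")
  grid <- cfm$seed_mask$grid
  arr <- array(NA_real_, grid$shape)
  arr[mask_linear_index(cfm$seed_mask)] <- cfm$fields[[which]]
  write_volume(arr, grid, path)
}

#' Read a parcel-to-network label table
#'
#' @param path TSV file with columns `parcel_id` and `network`.
#' @return data.frame with integer `parcel_id` and character `network`.
#' @export
read_network_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("parcel_id", "network") %in% names(tab)))
    stop("network table must have columns 'parcel_id' and 'network'")
  tab$parcel_id <- as.integer(tab$parcel_id)
  tab
}
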