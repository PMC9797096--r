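# Volumetric IO and the two preprocessing steps applied on top of released
# data: temporal highpass filtering and nuisance (CSF/WM) regression.

#' Construct a 4D volume time-series
#'
#' A `volume_series` holds a 4D array in native NIfTI axis order
#' (X, Y, Z, T), a 4x4 voxel-to-world affine, and the repetition time in
#' seconds. Input data are validated: at least two time points, an invertible
#' affine, and no non-finite voxels.
#'
#' @param data numeric 4D array, dimensions X x Y x Z x T.
#' @param affine 4x4 numeric voxel-to-world matrix.
#' @param tr repetition time in seconds.
#' @return An object of class `volume_series`.
#' @export
volume_series <- function(data, affine = diag(4), tr = 1) {
  if (length(dim(data)) != 4L)
    stopf("expected a 4-D array (X, Y, Z, T); got rank %d", length(dim(data)))
  if (dim(data)[4] < 2L) stopf("need at least 2 time points, got %d", dim(data)[4])
  nbad <- sum(!is.finite(data))
  if (nbad > 0) stopf("volume contains %d non-finite voxel values", nbad)
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || abs(det(affine)) < .Machine$double.eps)
    stopf("affine must be an invertible 4x4 matrix")
  if (!is.numeric(tr) || tr <= 0) stopf("tr must be a positive number of seconds")
  structure(list(data = data, affine = affine, tr = as.numeric(tr)),
            class = "volume_series")
}

#' @export
print.volume_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume_series> %d x %d x %d voxels, %d time points, TR %g s\n",
              d[1], d[2], d[3], d[4], x$tr))
  invisible(x)
}

#' Read a 4D NIfTI time-series
#'
#' @param path path to a 4D NIfTI-1 file.
#' @return A [volume_series()]; TR is taken from the 4th pixdim entry.
#' @export
read_series <- function(path) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 4L)
    stopf("'%s' has rank %d; expected rank 4 (X, Y, Z, T)",
          path, length(dim(img)))
  aff <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
  volume_series(array(as.numeric(img), dim(img)),
                affine = matrix(as.numeric(aff), 4, 4),
                tr = RNifti::pixdim(img)[4])
}

#' Write a volume series (or a 3D volume) as NIfTI
#'
#' @param series a [volume_series()], or a plain 3D array (mask/atlas).
#' @param path output path (`.nii` or `.nii.gz`).
#' @param affine affine used when `series` is a bare array.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path, affine = diag(4)) {
  if (inherits(series, "volume_series")) {
    img <- RNifti::asNifti(series$data)
    pd <- sqrt(colSums(series$affine[1:3, 1:3]^2))
    RNifti::pixdim(img) <- c(pd, series$tr)
    img <- RNifti::asNifti(img, datatype = "float")
    RNifti::sform(img) <- structure(series$affine, code = 2L)
  } else {
    img <- RNifti::asNifti(series)
    RNifti::sform(img) <- structure(affine, code = 2L)
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

# Read a 3D integer volume (mask / atlas).
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.numeric(img), dim(img)[1:3])
}

#' Extract the in-mask data matrix of a series
#'
#' Returns the T x V matrix of time-courses of the voxels inside a binary
#' mask, with columns in fixed lexicographic order (x fastest), plus the
#' linear voxel indices needed to reinsert values into the volume grid.
#'
#' @param series a [volume_series()] or 4D array.
#' @param mask 3D array, nonzero inside the region.
#' @return A `masked_matrix`: list with `values` (T x V), `voxels` (linear
#'   indices into the 3D grid), `dim` (grid shape).
#' @export
extract_masked_matrix <- function(series, mask) {
  data <- if (inherits(series, "volume_series")) series$data else series
  d <- dim(data)
  if (!all(dim(mask) == d[1:3]))
    stopf("mask grid %s does not match series grid %s",
          paste(dim(mask), collapse = "x"), paste(d[1:3], collapse = "x"))
  idx <- which(mask != 0)
  if (length(idx) == 0L) stopf("mask is empty")
  flat <- matrix(data, prod(d[1:3]), d[4])
  structure(list(values = t(flat[idx, , drop = FALSE]),
                 voxels = idx, dim = d[1:3]),
            class = "masked_matrix")
}

#' Reinsert a masked matrix into a full 4D array
#'
#' Inverse of [extract_masked_matrix()]: voxels outside the mask are set to
#' `fill`. The round trip is lossless on mask voxels.
#'
#' @param mm a `masked_matrix`.
#' @param fill value for out-of-mask voxels.
#' @return 4D array (X, Y, Z, T).
#' @export
insert_masked_matrix <- function(mm, fill = 0) {
  tdim <- nrow(mm$values)
  flat <- matrix(fill, prod(mm$dim), tdim)
  flat[mm$voxels, ] <- t(mm$values)
  array(flat, c(mm$dim, tdim))
}

# Accept a masked_matrix or a plain matrix; return list(values, rebuild fn).
.as_values <- function(x) {
  if (inherits(x, "masked_matrix")) {
    list(values = x$values,
         rebuild = function(v) { x$values <- v; x })
  } else list(values = as.matrix(x), rebuild = function(v) v)
}

#' Temporal highpass filter (hard DFT threshold)
#'
#' Removes the DC component and every Fourier component with frequency
#' strictly below `1/cutoff_seconds` Hz; all other components pass with unit
#' gain. Output columns are therefore exactly zero-mean.
#'
#' @param x T x V matrix or `masked_matrix`.
#' @param tr repetition time in seconds.
#' @param cutoff_seconds highpass cutoff period, default 2000 s.
#' @return filtered object of the same type as `x`.
#' @export
highpass_filter <- function(x, tr, cutoff_seconds = 2000) {
  xx <- .as_values(x)
  v <- xx$values
  tdim <- nrow(v)
  if (tdim < 4L) stopf("need at least 4 time points to filter, got %d", tdim)
  if (cutoff_seconds <= 2 * tr)
    stopf("cutoff_seconds (%g) must exceed 2 * tr (%g)", cutoff_seconds, 2 * tr)
  j <- seq_len(tdim) - 1L
  freq <- pmin(j, tdim - j) / (tdim * tr)   # two-sided DFT bin frequencies
  kill <- freq < 1 / cutoff_seconds         # includes DC (freq 0)
  fx <- stats::mvfft(v)
  fx[kill, ] <- 0
  out <- Re(stats::mvfft(fx, inverse = TRUE)) / tdim
  xx$rebuild(out)
}

#' Regress nuisance time-courses out of a data matrix
#'
#' Ordinary least squares of every column of `x` on the nuisance regressors
#' (an intercept is added internally), returning the residuals. Residual
#' columns are zero-mean and orthogonal to every regressor.
#'
#' @param x T x V matrix or `masked_matrix`.
#' @param regressors T x R matrix, R < T.
#' @return residual object of the same type as `x`.
#' @export
regress_nuisance <- function(x, regressors) {
  xx <- .as_values(x)
  v <- xx$values
  reg <- as.matrix(regressors)
  if (nrow(reg) != nrow(v))
    stopf("regressors have %d rows but data has %d time points",
          nrow(reg), nrow(v))
  if (ncol(reg) >= nrow(v)) stopf("need fewer regressors than time points")
  design <- cbind(`(intercept)` = 1, reg)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    bad <- setdiff(seq_len(ncol(design)), qrd$pivot[seq_len(qrd$rank)])
    nm <- colnames(design)[bad]
    if (is.null(nm)) nm <- paste0("column ", bad)
    stopf("rank-deficient regressor set; collinear: %s",
          paste(nm, collapse = ", "))
  }
  xx$rebuild(qr.resid(qrd, v))
}

#' Mean time-course over a mask
#'
#' Unweighted average across all voxels inside the mask at each time point,
#' e.g. to build CSF/WM nuisance regressors.
#'
#' @param series a [volume_series()] or 4D array.
#' @param mask 3D binary array.
#' @return numeric vector of length T.
#' @export
mask_mean_timecourse <- function(series, mask) {
  rowMeans(extract_masked_matrix(series, mask)$values)
}
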