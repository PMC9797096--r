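# Spatially-restricted group ICA: temporal concatenation across subjects,
# PCA whitening to the requested model order, then symmetric fixed-point ICA
# (log-cosh contrast) unmixing the voxel dimension so that components are
# spatial maps over seed voxels.

#' Concatenate per-subject seed matrices for group ICA
#'
#' Each subject-session block is demeaned and variance-normalized per voxel
#' column, then the blocks are stacked in the given order (temporal
#' concatenation).
#'
#' @param mats list of T_s x V matrices or `masked_matrix` objects sharing V.
#' @param ids optional block identifiers (defaults to list names/index).
#' @return list of class `group_matrix`: `values` ((sum T_s) x V), `blocks`
#'   data.frame(id, rows).
#' @export
concat_subjects <- function(mats, ids = NULL) {
  if (length(mats) == 0L) stopf("no matrices to concatenate")
  vals <- lapply(mats, function(m) .as_values(m)$values)
  if (is.null(ids)) ids <- if (!is.null(names(mats))) names(mats)
    else as.character(seq_along(mats))
  v <- ncol(vals[[1]])
  for (i in seq_along(vals))
    if (ncol(vals[[i]]) != v)
      stopf("subject '%s' has %d voxels; expected %d", ids[i], ncol(vals[[i]]), v)
  norm <- lapply(vals, function(m) scale_cols(demean_cols(m)))
  structure(list(values = do.call(rbind, norm),
                 blocks = data.frame(id = ids,
                                     rows = vapply(vals, nrow, integer(1)),
                                     stringsAsFactors = FALSE)),
            class = "group_matrix")
}

# Symmetric decorrelation: W <- (W W^T)^{-1/2} W.
sym_decorrelate <- function(w) {
  e <- eigen(tcrossprod(w), symmetric = TRUE)
  e$vectors %*% diag(1 / sqrt(pmax(e$values, .Machine$double.eps)),
                     nrow(w)) %*% t(e$vectors) %*% w
}

#' Group spatial ICA on a seed-region matrix
#'
#' Whitens the (temporally concatenated) data to exactly `d` principal
#' components over the voxel dimension and runs symmetric fixed-point ICA
#' with the log-cosh contrast. Components are spatial maps, z-scored over
#' seed voxels, ordered by explained variance; group mixing time-courses are
#' recovered by least squares.
#'
#' @param x `group_matrix` from [concat_subjects()] or a plain N x V matrix.
#' @param d model order (number of components), 1 <= d <= numerical rank.
#' @param rng_seed seed for the random orthogonal initialization.
#' @param tol convergence tolerance on the unmixing update.
#' @param maxit maximum fixed-point iterations per restart.
#' @param restarts maximum restarts (seeds `rng_seed + 1, ...`) on
#'   non-convergence.
#' @return object of class `ic_result`: `dimension`, `spatial_maps` (d x V),
#'   `mixing` (N x d), `explained_variance`, `iterations`, `rng_seed`.
#' @export
group_spatial_ica <- function(x, d, rng_seed = 1, tol = 1e-6, maxit = 1000L,
                              restarts = 5L) {
  vals <- if (inherits(x, "group_matrix")) x$values else as.matrix(x)
  vals <- demean_cols(vals)
  n <- nrow(vals); v <- ncol(vals)
  if (d < 1 || d > min(n, v))
    stopf("model order d=%d outside 1..min(rows, voxels)=%d", d, min(n, v))
  cp <- crossprod(vals)                       # V x V
  e <- eigen(cp, symmetric = TRUE)
  rank <- sum(e$values > max(e$values) * 1e-10)
  if (d > rank)
    stopf("model order d=%d exceeds numerical rank %d of the data", d, rank)
  vd <- e$vectors[, seq_len(d), drop = FALSE] # V x d, orthonormal
  y <- sqrt(v) * t(vd)                        # d x V whitened spatial data

  run_ica <- function(seed) {
    w <- with_seed(seed, matrix(stats::rnorm(d * d), d, d))
    w <- sym_decorrelate(w)
    for (it in seq_len(maxit)) {
      wy <- w %*% y                           # d x V current estimates
      gwy <- tanh(wy)
      w1 <- gwy %*% t(y) / v - diag(rowMeans(1 - gwy^2), d) %*% w
      w1 <- sym_decorrelate(w1)
      delta <- max(abs(abs(diag(w1 %*% t(w))) - 1))
      w <- w1
      if (delta < tol) return(list(w = w, iterations = it))
    }
    NULL
  }
  res <- NULL
  for (r in 0:restarts) {
    res <- run_ica(rng_seed + r)
    if (!is.null(res)) break
  }
  if (is.null(res))
    stopf("fixed-point ICA did not converge after %d restarts (tol %g)",
          restarts, tol)

  s <- res$w %*% y                            # d x V raw spatial sources
  maps <- t(apply(s, 1L, function(row) (row - mean(row)) / stats::sd(row)))
  if (d == 1L) maps <- matrix(maps, 1L, v)
  # Mixing time-courses by least squares of the data on the z-scored maps.
  design <- cbind(1, t(maps))                 # V x (d+1)
  coef <- qr.coef(qr(design), t(vals))        # (d+1) x N
  mixing <- t(coef[-1L, , drop = FALSE])      # N x d
  ev <- vapply(seq_len(d), function(k)
    sum(mixing[, k]^2) * sum(maps[k, ]^2), numeric(1))
  ev <- ev / max(sum(vals^2), .Machine$double.eps)
  ord <- order(ev, decreasing = TRUE)
  structure(list(dimension = d,
                 spatial_maps = maps[ord, , drop = FALSE],
                 mixing = mixing[, ord, drop = FALSE],
                 explained_variance = ev[ord],
                 iterations = res$iterations, rng_seed = rng_seed),
            class = "ic_result")
}

#' @export
print.ic_result <- function(x, ...) {
  cat(sprintf("<ic_result> d = %d, %d voxels, %d mixing rows\n",
              x$dimension, ncol(x$spatial_maps), nrow(x$mixing)))
  invisible(x)
}

#' Resolve ICA sign indeterminacy by positive skewness
#'
#' Flips each spatial map (and its mixing column) so that the map's skewness
#' is nonnegative; cluster "hotspots" then carry positive weights. Zero-skew
#' maps are left unchanged and counted in attribute `zero_skew`.
#'
#' @param ic an `ic_result`.
#' @return the re-oriented `ic_result`.
#' @export
orient_components <- function(ic) {
  stopifnot(inherits(ic, "ic_result"))
  zero <- 0L
  for (k in seq_len(ic$dimension)) {
    sk <- skewness(ic$spatial_maps[k, ])
    if (sk < 0) {
      ic$spatial_maps[k, ] <- -ic$spatial_maps[k, ]
      ic$mixing[, k] <- -ic$mixing[, k]
    } else if (sk == 0) zero <- zero + 1L
  }
  attr(ic, "zero_skew") <- zero
  ic
}
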