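# Dual regression: seed-restricted group IC maps -> per-subject time-courses
# (stage 1) -> per-subject whole-brain beta/t/Z maps (stage 2), plus the
# group-level one-sample map with optional sign-flip permutation inference.

#' Stage 1: subject time-courses from group spatial maps
#'
#' Joint multiple regression of each time point's seed-voxel pattern on all
#' d spatial maps simultaneously; the recovered least-squares time-courses
#' are variance-normalized to SD 1.
#'
#' @param seed_mm subject seed-region data, `masked_matrix` or T x V matrix.
#' @param spatial_maps d x V matrix (rows on the same voxel ordering).
#' @return T x d matrix of unit-SD component time-courses.
#' @export
stage1_timecourses <- function(seed_mm, spatial_maps) {
  y <- .as_values(seed_mm)$values
  m <- t(as.matrix(spatial_maps))                  # V x d design
  if (nrow(m) != ncol(y))
    stopf("spatial maps have %d voxels but data has %d", nrow(m), ncol(y))
  y <- demean_cols(t(y))                           # V x T, demeaned per column
  m <- demean_cols(m)
  sv <- svd(m, nu = 0, nv = 0)$d
  if (min(sv) <= 0 || max(sv) / min(sv) > 1e4)     # cond(M'M) = cond(M)^2
    stopf("spatial map design is collinear or degenerate (condition number %.3g)",
          if (min(sv) > 0) (max(sv) / min(sv))^2 else Inf)
  tc <- t(qr.coef(qr(m), y))                       # T x d
  scale_cols(demean_cols(tc))
}

#' Stage 2: subject whole-brain component maps
#'
#' Regresses every voxel's time-course jointly on all d stage-1 time-courses
#' (plus intercept). Per voxel and component: beta, t = beta/SE with
#' T - d - 1 residual df, and Z = qnorm(pt(t)) clipped at +/- 38.
#'
#' @param mm whole-brain data, `masked_matrix` or T x V matrix.
#' @param timecourses T x d matrix from [stage1_timecourses()].
#' @param subject,session optional identifiers stored in the result.
#' @return object of class `subject_fc_map`: `beta`, `t`, `z` (d x V),
#'   `voxels`/`dim` when input was masked, `df`, ids.
#' @export
stage2_subject_maps <- function(mm, timecourses, subject = NA, session = NA) {
  xx <- .as_values(mm)
  y <- xx$values
  tc <- as.matrix(timecourses)
  tdim <- nrow(y); d <- ncol(tc)
  if (nrow(tc) != tdim)
    stopf("time-courses have %d rows but data has %d time points", nrow(tc), tdim)
  if (tdim <= d + 1L)
    stopf("need T > d + 1 (T=%d, d=%d)", tdim, d)
  design <- cbind(1, tc)
  qrd <- qr(design)
  coef <- qr.coef(qrd, y)                          # (d+1) x V
  res <- y - design %*% coef
  df <- tdim - d - 1L
  sigma2 <- colSums(res^2) / df
  xtxinv <- chol2inv(qr.R(qrd))                    # (X'X)^{-1}
  beta <- coef[-1L, , drop = FALSE]
  se <- sqrt(outer(diag(xtxinv)[-1L], sigma2))
  tstat <- beta / se
  deg <- se == 0
  tstat[deg] <- ifelse(beta[deg] == 0, 0, sign(beta[deg]) * Inf)
  z <- t_to_z(tstat, df)
  out <- list(beta = beta, t = tstat, z = z, df = df,
              subject = subject, session = session)
  if (inherits(mm, "masked_matrix")) {
    out$voxels <- mm$voxels
    out$dim <- mm$dim
  }
  structure(out, class = "subject_fc_map")
}

#' Average a subject's session maps
#'
#' Averages the Z maps of one subject's sessions (element-wise); the result
#' is invariant to session ordering and feeds the group-level test with one
#' observation per subject.
#'
#' @param maps list of `subject_fc_map` for one subject.
#' @return a `subject_fc_map` with averaged `z` (beta/t dropped).
#' @export
average_sessions <- function(maps) {
  stopifnot(length(maps) >= 1)
  z <- Reduce(`+`, lapply(maps, function(m) m$z)) / length(maps)
  out <- list(z = z, df = NA, subject = maps[[1]]$subject, session = NA,
              voxels = maps[[1]]$voxels, dim = maps[[1]]$dim)
  structure(out, class = "subject_fc_map")
}

#' Group-level one-sample map across subjects
#'
#' Voxelwise one-sample t test of the subject Z maps against zero, converted
#' to Z (clipped at +/- 38), with optional sign-flip permutation p-values.
#' Zero-variance voxels map to 0 (if the mean is also 0) or +/- 38, counted
#' in a warning. The result is exactly invariant to subject ordering.
#'
#' @param subject_maps list of `subject_fc_map`, one per subject (average
#'   sessions first, see [average_sessions()]).
#' @param n_permutations number of sign-flip permutations (0 = none).
#' @param rng_seed seed for the permutation signs.
#' @return object of class `group_fc_map`: `z` (d x V), `n`, optional `p`,
#'   `n_permutations`, `rng_seed`, `n_degenerate`.
#' @export
group_map <- function(subject_maps, n_permutations = 0L, rng_seed = 1) {
  n <- length(subject_maps)
  if (n < 2L) stopf("need at least 2 subjects, got %d", n)
  d <- nrow(subject_maps[[1]]$z)
  v <- ncol(subject_maps[[1]]$z)
  zs <- lapply(subject_maps, function(m) {
    if (!all(dim(m$z) == c(d, v))) stopf("subject map dimensions differ")
    m$z
  })
  one_sample <- function(x) {                      # x: n x V
    m <- colMeans(x)
    s <- sqrt(colSums(sweep(x, 2L, m)^2) / (n - 1))
    t <- m / (s / sqrt(n))
    list(t = t, degenerate = s == 0, mean = m)
  }
  z <- matrix(0, d, v)
  p <- if (n_permutations > 0) matrix(NA_real_, d, v) else NULL
  ndeg <- 0L
  signs <- if (n_permutations > 0)
    with_seed(rng_seed,
              matrix(sample(c(-1, 1), n * n_permutations, replace = TRUE),
                     n, n_permutations))
  for (k in seq_len(d)) {
    x <- do.call(rbind, lapply(zs, function(m) m[k, ]))
    os <- one_sample(x)
    zk <- t_to_z(os$t, n - 1)
    if (any(os$degenerate)) {
      ndeg <- ndeg + sum(os$degenerate & os$mean != 0)   # clipped cells only
      zk[os$degenerate] <- ifelse(os$mean[os$degenerate] == 0, 0,
                                  sign(os$mean[os$degenerate]) * Z_CLIP)
    }
    z[k, ] <- zk
    if (n_permutations > 0) {
      tobs <- abs(os$t)
      tobs[os$degenerate] <- abs(os$mean[os$degenerate]) * Inf
      tobs[os$degenerate & os$mean == 0] <- 0
      count <- rep(1L, v)                          # includes the identity flip
      for (b in seq_len(n_permutations)) {
        xb <- x * signs[, b]
        ob <- one_sample(xb)
        tb <- abs(ob$t)
        tb[ob$degenerate] <- abs(ob$mean[ob$degenerate]) * Inf
        tb[ob$degenerate & ob$mean == 0] <- 0
        count <- count + (tb >= tobs)
      }
      p[k, ] <- count / (n_permutations + 1L)
    }
  }
  if (ndeg > 0)
    warnf("%d zero-variance voxel/component cells set to 0 or +/-%d", ndeg, Z_CLIP)
  structure(list(z = z, n = n, p = p, n_permutations = n_permutations,
                 rng_seed = if (n_permutations > 0) rng_seed else NA,
                 n_degenerate = ndeg,
                 voxels = subject_maps[[1]]$voxels,
                 dim = subject_maps[[1]]$dim),
            class = "group_fc_map")
}
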