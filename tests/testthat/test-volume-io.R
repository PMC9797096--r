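# NIfTI round trips, masking bijection, highpass filter, nuisance regression.

test_that("write/read round trip preserves data, affine and TR", {
  arr <- array(rnorm(4 * 4 * 4 * 10), c(4, 4, 4, 10))
  aff <- diag(c(2, 2, 2, 1)); aff[1:3, 4] <- c(-10, -20, -5)
  vs <- volume_series(arr, affine = aff, tr = 1.0)
  f <- tempfile(fileext = ".nii.gz")
  write_series(vs, f)
  back <- read_series(f)
  expect_lt(max(abs(back$data - arr)), 1e-6)
  expect_equal(back$affine, aff, tolerance = 1e-6)
  expect_equal(back$tr, 1.0)
  unlink(f)
})

test_that("reading a 3D file errors naming expected rank 4", {
  f <- tempfile(fileext = ".nii.gz")
  write_series(array(1, c(4, 4, 4)), f)
  expect_error(read_series(f), "rank 4")
  unlink(f)
})

test_that("volume_series validates shape, finiteness, affine, T", {
  expect_error(volume_series(array(1, c(3, 3, 3))), "4-D")
  expect_error(volume_series(array(1, c(3, 3, 3, 1))), "2 time points")
  bad <- array(1, c(2, 2, 2, 3)); bad[1, 1, 1, 2] <- NaN; bad[2, 1, 1, 1] <- Inf
  expect_error(volume_series(bad), "2 non-finite")
  expect_error(volume_series(array(1, c(2, 2, 2, 3)), affine = matrix(0, 4, 4)),
               "invertible")
})

test_that("masking extracts the right voxels and inverts losslessly", {
  arr <- array(rnorm(5 * 4 * 3 * 7), c(5, 4, 3, 7))
  vs <- volume_series(arr)
  one <- array(0, c(5, 4, 3)); one[2, 3, 1] <- 1
  mm1 <- extract_masked_matrix(vs, one)
  expect_equal(ncol(mm1$values), 1L)
  expect_equal(as.numeric(mm1$values), as.numeric(arr[2, 3, 1, ]))

  allm <- array(1, c(5, 4, 3))
  expect_equal(ncol(extract_masked_matrix(vs, allm)$values), 60L)

  mask <- array(rbinom(60, 1, 0.4), c(5, 4, 3))
  mask[1, 1, 1] <- 1
  mm <- extract_masked_matrix(vs, mask)
  rebuilt <- insert_masked_matrix(mm, fill = 0)
  idx <- which(mask != 0)
  flat_in <- matrix(arr, 60, 7); flat_out <- matrix(rebuilt, 60, 7)
  expect_identical(flat_out[idx, ], flat_in[idx, ])
  expect_true(all(flat_out[-idx, ] == 0))

  expect_error(extract_masked_matrix(vs, array(0, c(5, 4, 3))), "empty")
  expect_error(extract_masked_matrix(vs, array(1, c(4, 4, 3))), "grid")
})

test_that("highpass removes DC and low frequencies, passes the rest unchanged", {
  # constant column -> zeros
  x <- matrix(5, 100, 2)
  expect_true(all(abs(highpass_filter(x, tr = 1)) < 1e-12))

  # T=900, tr=1, cutoff=2000: only the DC bin is below 1/2000 Hz, so the
  # filter must equal plain demeaning
  x <- matrix(rnorm(900 * 3), 900, 3)
  hp <- highpass_filter(x, tr = 1, cutoff_seconds = 2000)
  expect_lt(max(abs(hp - scale(x, scale = FALSE))), 1e-9)

  # unit sine of period 10 s is far above cutoff: passes with unit gain
  tt <- seq_len(900)
  s <- sin(2 * pi * tt / 10)
  out <- highpass_filter(matrix(s), tr = 1, cutoff_seconds = 2000)
  expect_lt(max(abs(out - (s - mean(s)))), 1e-6)

  # oracle: direct DFT zeroing on random data with an aggressive cutoff
  tdim <- 64; tr <- 2; cutoff <- 40
  x <- matrix(rnorm(tdim * 4), tdim, 4)
  fx <- stats::mvfft(x)
  freq <- pmin(0:(tdim - 1), tdim - (0:(tdim - 1))) / (tdim * tr)
  fx[freq < 1 / cutoff, ] <- 0
  oracle <- Re(stats::mvfft(fx, inverse = TRUE)) / tdim
  expect_lt(max(abs(highpass_filter(x, tr, cutoff) - oracle)), 1e-9)

  expect_error(highpass_filter(matrix(rnorm(6), 3, 2), tr = 1), "4 time points")
  expect_error(highpass_filter(matrix(rnorm(40), 20, 2), tr = 1,
                               cutoff_seconds = 1.5), "exceed")
})

test_that("nuisance regression orthogonalizes and matches the normal equations", {
  set.seed(1)
  tdim <- 200
  reg <- cbind(rnorm(tdim), rnorm(tdim))
  x <- matrix(rnorm(tdim * 50), tdim, 50)
  res <- regress_nuisance(x, reg)
  # residuals zero-mean and orthogonal to regressors
  expect_lt(max(abs(colMeans(res))), 1e-10)
  ip <- crossprod(scale(reg), res) / tdim
  expect_lt(max(abs(ip)), 1e-8)
  # normal-equations oracle
  design <- cbind(1, reg)
  oracle <- x - design %*% solve(crossprod(design), crossprod(design, x))
  expect_lt(max(abs(res - oracle)), 1e-8)

  # a column equal to a regressor is annihilated
  x2 <- cbind(reg[, 1], x[, 1])
  expect_lt(max(abs(regress_nuisance(x2, reg)[, 1])), 1e-10)

  # regressors orthogonal to the data leave the demeaned data unchanged
  xo <- qr.resid(qr(cbind(1, reg)), x)
  expect_lt(max(abs(regress_nuisance(xo, reg) - xo)), 1e-8)

  # collinear regressors are named
  expect_error(regress_nuisance(x, cbind(a = reg[, 1], b = 2 * reg[, 1])),
               "collinear")
})

test_that("filter and regression commute when regressors are filtered", {
  set.seed(2)
  tdim <- 128
  x <- matrix(rnorm(tdim * 10), tdim, 10)
  reg <- matrix(rnorm(tdim * 2), tdim, 2)
  regf <- highpass_filter(reg, tr = 1, cutoff_seconds = 30)
  a <- regress_nuisance(highpass_filter(x, 1, 30), regf)
  b <- highpass_filter(regress_nuisance(x, regf), 1, 30)
  expect_lt(max(abs(a - b)), 1e-6)
})

test_that("mask mean time-course averages voxels unweighted", {
  arr <- array(rnorm(3 * 3 * 2 * 5), c(3, 3, 2, 5))
  mask <- array(0, c(3, 3, 2)); mask[1, 1, 1] <- 1; mask[3, 2, 2] <- 1
  expect_equal(mask_mean_timecourse(volume_series(arr), mask),
               (arr[1, 1, 1, ] + arr[3, 2, 2, ]) / 2)
})
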