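# Generator contracts: template disjointness, determinism, score splits,
# noise-free rank, AR(1) calibration, null fear effect.

test_that("reference templates are binary, disjoint, inside the brain mask", {
  ts <- make_reference_templates(2, c(20, 20, 10), rng_seed = 1)
  expect_length(ts$templates, 2)
  for (tm in ts$templates) {
    expect_true(all(tm %in% c(0, 1)))
    expect_gt(sum(tm), 0)
    expect_true(all(ts$brain_mask[tm == 1] == 1))
  }
  expect_equal(sum(ts$templates[[1]] * ts$templates[[2]]), 0)

  one <- make_reference_templates(1, c(15, 15, 8), rng_seed = 3)$templates[[1]]
  expect_equal(stats::cor(as.numeric(one), as.numeric(one)), 1.0)

  a <- make_reference_templates(7, c(40, 40, 20), rng_seed = 7)
  b <- make_reference_templates(7, c(40, 40, 20), rng_seed = 7)
  expect_identical(a, b)
  ov <- Reduce(`+`, a$templates)
  expect_true(all(ov <= 1))
  expect_lt(sum(ov), 0.8 * sum(a$brain_mask))
})

test_that("too-small grids raise a sizing error naming the requirement", {
  expect_error(make_reference_templates(7, c(6, 6, 4), rng_seed = 1),
               "at least")
})

test_that("fear scores split into the expected groups", {
  s <- make_fear_scores(172, c(44.0, 55.2), c(4.9, 4.5), rng_seed = 1)
  expect_length(s, 172)
  expect_equal(as.vector(table(median_split(s))), c(86, 86))
  expect_lt(abs(mean(s[attr(s, "generating_group") == "low"]) - 44.0),
            3 * 4.9 / sqrt(86))
  expect_lt(abs(mean(s[attr(s, "generating_group") == "high"]) - 55.2),
            3 * 4.5 / sqrt(86))

  s4 <- make_fear_scores(4, c(0, 0), c(1, 1), rng_seed = 2)
  expect_equal(as.vector(table(median_split(s4))), c(2, 2))

  # near-zero variance: split recovers the generating groups exactly
  sg <- make_fear_scores(100, c(10, 20), c(0.001, 0.001), rng_seed = 3)
  expect_identical(as.character(median_split(sg)),
                   attr(sg, "generating_group"))

  expect_error(make_fear_scores(10, c(1, 2), c(0, 1)), "positive")
})

test_that("noise-free cohort has seed-region rank equal to K_true", {
  cfg <- synthetic_config(n_subjects = 1, n_sessions_per_subject = 1,
                          n_timepoints = 60, network_snr = 1e12,
                          subject_sd = 0, rng_seed = 5)
  co <- simulate_cohort(cfg)
  mm <- extract_masked_matrix(co$subjects[[1]][[1]], co$seed_mask)
  x <- scale(mm$values, scale = FALSE)
  sv <- svd(x, nu = 0, nv = 0)$d
  expect_equal(sum(sv > sv[1] * 1e-8), 3L)
})

test_that("cohort generation is bit-reproducible for a fixed seed", {
  cfg <- synthetic_config(n_subjects = 2, n_sessions_per_subject = 2,
                          n_timepoints = 40, rng_seed = 42)
  a <- simulate_cohort(cfg); b <- simulate_cohort(cfg)
  expect_identical(a$subjects[[1]][[2]]$data, b$subjects[[1]][[2]]$data)
  expect_identical(a$truth, b$truth)
  expect_identical(a$covariates, b$covariates)

  d1 <- file.path(tempdir(), "coh1"); d2 <- file.path(tempdir(), "coh2")
  make_cohort(cfg, d1); make_cohort(cfg, d2)
  expect_identical(readBin(file.path(d1, "truth.json"), "raw", 1e6),
                   readBin(file.path(d2, "truth.json"), "raw", 1e6))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("latent time-courses are zero-mean and assignment injective", {
  co <- simulate_cohort(small_config(rng_seed = 9))
  for (m in co$truth$latents[1:3])
    expect_lt(max(abs(colMeans(m))), 1e-12)
  a <- co$truth$template_assignment
  expect_equal(length(unique(a)), length(a))
})

test_that("generated noise matches the requested AR(1) coefficient", {
  for (phi in c(0, 0.3, 0.6)) {
    x <- srica:::with_seed(13, srica:::ar1_noise(2000, 30, sd = 1, phi = phi))
    ac <- mean(vapply(seq_len(30), function(j)
      stats::cor(x[-1, j], x[-2000, j]), numeric(1)))
    expect_lt(abs(ac - phi), 0.05)
    expect_lt(abs(stats::sd(x) - 1), 0.05)
  }
})

test_that("zero fear slope leaves subregion coupling balanced across groups", {
  # Monte-Carlo: with slope 0, the two-sample t on the designated subregion's
  # mean coupling stays small in nearly all replicates
  nseeds <- 100
  tvals <- vapply(seq_len(nseeds), function(s) {
    cfg <- synthetic_config(
      grid_shape = c(24, 24, 12), n_subjects = 12,
      n_sessions_per_subject = 1, n_timepoints = 30,
      fear_effect = list(label = "Co", network = 1, slope = 0),
      rng_seed = 1000 + s)
    co <- simulate_cohort(cfg)
    idx <- which(co$seed_mask != 0)
    nm <- cfg$seed_region_spec$name[match(co$seed_atlas[idx],
                                          cfg$seed_region_spec$label)]
    covox <- idx[nm == "Co"]
    grp <- median_split(co$covariates$fear_score)
    # mean coupling proxy: regression of Co voxels on the latent time-course
    cop <- vapply(seq_len(cfg$n_subjects), function(i) {
      dat <- matrix(co$subjects[[i]][[1]]$data, prod(cfg$grid_shape),
                    cfg$n_timepoints)[covox, , drop = FALSE]
      ct <- co$truth$latents[[sprintf("sub-%02d_ses-01", i)]][, 1]
      mean(dat %*% ct) / sum(ct^2)
    }, numeric(1))
    unname(stats::t.test(cop[grp == "low"], cop[grp == "high"],
                         var.equal = TRUE)$statistic)
  }, numeric(1))
  expect_gte(mean(abs(tvals) < 3), 0.95)
})

test_that("make_cohort writes a complete, reloadable tree", {
  d <- file.path(tempdir(), "cohw")
  cfg <- synthetic_config(n_subjects = 2, n_sessions_per_subject = 2,
                          n_timepoints = 40, rng_seed = 8)
  co <- make_cohort(cfg, d)
  expect_true(file.exists(file.path(d, "sub-01", "ses-02", "func.nii.gz")))
  expect_true(file.exists(file.path(d, "participants.tsv")))
  back <- load_cohort(d)
  expect_equal(length(back$subjects), 2)
  expect_lt(max(abs(back$subjects[[1]][[1]]$data - co$subjects[[1]][[1]]$data)),
            1e-5)
  expect_identical(back$seed_atlas, co$seed_atlas + 0)
  expect_equal(back$covariates$fear_score, co$covariates$fear_score,
               tolerance = 1e-6)
  unlink(d, recursive = TRUE)
})

test_that("config validation catches inconsistent shapes", {
  expect_error(synthetic_config(grid_shape = c(10, 10, 4)), "8x|too small")
  expect_error(synthetic_config(loading_matrix = matrix(1, 5, 3)),
               "5 rows")
  expect_error(synthetic_config(n_networks = 8,
                                loading_matrix = matrix(1, 9, 8)),
               "templates")
  expect_error(synthetic_config(fear_effect = list(label = "nope",
                                                   network = 1, slope = 1)),
               "subregion")
})
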