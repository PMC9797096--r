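# Parcel extraction oracle, mixed-model behavior, effect contrasts,
# ranking statistic, summary t test, fear analysis, test/validation maps.

# Balanced synthetic parcel table with known structure.
sim_table <- function(n_part = 12, regions = letters[1:4], comps = paste0("IC", 1:3),
                      subject_sd = 1, sigma = 1, effects = NULL, seed = 1) {
  set.seed(seed)
  tab <- expand.grid(participant = sprintf("p%02d", seq_len(n_part)),
                     hemisphere = c("L", "R"), region = regions,
                     component = comps, stringsAsFactors = FALSE)
  b <- stats::rnorm(n_part, 0, subject_sd)
  tab$z <- b[match(tab$participant, sprintf("p%02d", seq_len(n_part)))] +
    stats::rnorm(nrow(tab), 0, sigma)
  if (!is.null(effects))
    for (e in effects)
      tab$z[tab$region == e$region & tab$component == e$component] <-
        tab$z[tab$region == e$region & tab$component == e$component] + e$delta
  tab
}

test_that("parcel extraction equals brute-force per-label averaging", {
  set.seed(10)
  g <- c(8, 8, 4)
  atlas <- array(sample(0:5, prod(g), replace = TRUE), g)
  lookup <- data.frame(label = 1:5, name = paste0("r", c(1, 2, 3, 1, 2)),
                       hemisphere = c("L", "L", "L", "R", "R"))
  voxels <- which(array(TRUE, g))
  z <- matrix(rnorm(2 * length(voxels)), 2)
  fm <- structure(list(z = z, voxels = voxels, dim = g),
                  class = "subject_fc_map")
  tab <- extract_parcel_z(fm, atlas, lookup, participant = "p1")
  for (i in 1:5) {
    sel <- which(atlas[voxels] == i)
    for (k in 1:2) {
      got <- tab$z[tab$region == lookup$name[i] &
                     tab$hemisphere == lookup$hemisphere[i] &
                     tab$component == paste0("IC", k)]
      expect_equal(got, mean(z[k, sel]), tolerance = 1e-12)
    }
  }
  # constant map -> every region mean equals the constant
  fmc <- structure(list(z = matrix(2.5, 1, length(voxels)), voxels = voxels,
                        dim = g), class = "subject_fc_map")
  expect_true(all(extract_parcel_z(fmc, atlas, lookup, "p")$z == 2.5))
  # unknown label errors; empty label warns and is omitted
  expect_error(extract_parcel_z(fm, atlas, lookup[1:3, ], "p"), "absent")
  lookup2 <- rbind(lookup, data.frame(label = 9, name = "ghost",
                                      hemisphere = "L"))
  expect_warning(t2 <- extract_parcel_z(fm, atlas, lookup2, "p"), "omitted")
  expect_false("ghost" %in% t2$region)
})

test_that("mixed model reduces to OLS when participant variance is zero", {
  tab <- sim_table(n_part = 20, subject_sd = 0, seed = 2)
  fit <- fit_lmm(tab)
  tabf <- srica:::.prep_table(tab)
  ols <- stats::lm(z ~ hemisphere + component * region, data = tabf)
  expect_lt(max(abs(lme4::fixef(fit) - stats::coef(ols))), 1e-6)
})

test_that("mixed model recovers variance components and fixed effects", {
  # n chosen so the REML SD estimate's sampling error (~1/sqrt(2n)) sits
  # well inside the 20% check band
  tab <- sim_table(n_part = 80, regions = letters[1:3], comps = c("IC1", "IC2"),
                   subject_sd = 1, sigma = 1,
                   effects = list(list(region = "a", component = "IC1",
                                       delta = 1.5)), seed = 1)
  fit <- fit_lmm(tab)
  vc <- as.data.frame(lme4::VarCorr(fit))
  expect_lt(abs(vc$sdcor[vc$grp == "participant"] - 1), 0.2)
  # duplicating every row leaves the fixed effects essentially unchanged
  fit2 <- fit_lmm(rbind(tab, tab))
  expect_lt(max(abs(lme4::fixef(fit) - lme4::fixef(fit2))), 1e-6)
})

test_that("type-III interaction F is invariant to level reordering", {
  tab <- sim_table(seed = 3)
  f1 <- anova_type3(fit_lmm(tab))
  tab2 <- tab
  tab2$region <- factor(tab2$region, levels = rev(sort(unique(tab2$region))))
  f2 <- anova_type3(fit_lmm(tab2))
  i1 <- f1$f[f1$term == "component:region"]
  i2 <- f2$f[f2$term == "component:region"]
  expect_equal(i1, i2, tolerance = 1e-8)
})

test_that("with zero participant variance the ANOVA matches the fixed-effects oracle", {
  tab <- sim_table(n_part = 16, subject_sd = 0, seed = 4)
  # remove empirical participant means so the REML variance estimate hits
  # the zero boundary and the mixed fit reduces exactly to OLS
  tab$z <- tab$z - ave(tab$z, tab$participant) + mean(tab$z)
  a <- anova_type3(fit_lmm(tab))
  tabf <- srica:::.prep_table(tab)
  oracle <- stats::anova(stats::lm(z ~ hemisphere + component * region,
                                   data = tabf))
  for (trm in c("hemisphere", "component", "region")) {
    expect_equal(a$f[a$term == trm], oracle[trm, "F value"], tolerance = 1e-4)
  }
  expect_equal(a$f[a$term == "component:region"],
               oracle["component:region", "F value"], tolerance = 1e-4)
})

test_that("effect contrasts equal level-minus-mean-of-others arithmetic", {
  # EMMs (3, 1, 1) for three maps in one region -> contrasts (+2, -1, -1)
  tab <- expand.grid(participant = sprintf("p%d", 1:40),
                     hemisphere = c("L", "R"), region = c("a", "b"),
                     component = paste0("IC", 1:3), stringsAsFactors = FALSE)
  mu <- c(IC1 = 3, IC2 = 1, IC3 = 1)
  set.seed(5)
  tab$z <- mu[tab$component] + rnorm(nrow(tab), 0, 0.01)
  ct <- emm_contrasts(fit_lmm(tab))
  a1 <- ct[ct$region == "a", ]
  expect_equal(a1$estimate[a1$component == "IC1"], 2, tolerance = 0.01)
  expect_equal(a1$estimate[a1$component == "IC2"], -1, tolerance = 0.01)
  expect_equal(a1$estimate[a1$component == "IC3"], -1, tolerance = 0.01)
  # all-equal EMMs -> zero contrasts and z-ratios
  tab$z <- 2 + rnorm(nrow(tab), 0, 1)
  ct0 <- emm_contrasts(fit_lmm(tab))
  expect_lt(max(abs(ct0$estimate)), 0.5)
  # Bonferroni family = whole table
  expect_true(all(ct0$p_adj >= pmin(1, ct0$p * nrow(ct0)) - 1e-12))
})

test_that("ranking statistic sums, thresholds and orders correctly", {
  z <- matrix(0, 3, 3)
  z[1, 2] <- 2; z[1, 3] <- 3; z[2, 3] <- 1
  z[lower.tri(z)] <- -t(z)[lower.tri(z)]
  rk <- rank_nuclei(z)
  expect_equal(attr(rk, "sums"), c(5, -1, -4), ignore_attr = TRUE)
  expect_equal(nrow(rk), 1L)
  expect_equal(rk$rank, 1L)
  expect_equal(rk$summed_z_ratio, 5)

  expect_equal(nrow(rank_nuclei(matrix(0, 4, 4))), 0L)

  set.seed(6)
  a <- matrix(rnorm(81), 9, 9); z9 <- a - t(a)
  rownames(z9) <- colnames(z9) <- paste0("n", 1:9)
  rk9 <- rank_nuclei(z9)
  expect_lt(abs(sum(attr(rk9, "sums"))), 1e-10)
  sums <- rowSums(z9)
  keep <- sums[sums > 0]
  expect_equal(rk9$subregion, names(sort(keep, decreasing = TRUE)))
  expect_equal(rk9$rank, seq_along(keep))

  bad <- z9; bad[1, 2] <- bad[1, 2] + 1e-3
  expect_error(rank_nuclei(bad), "antisymmetric")
})

test_that("summary-statistics t test reproduces published group comparison", {
  res <- two_sample_t(86, 44.0, 4.9, 86, 55.2, 4.5)
  expect_equal(res$df, 170)
  expect_lt(abs(abs(res$t) - 15.47), 0.2)
  expect_lt(res$p, 1e-4)

  expect_equal(two_sample_t(10, 5, 1, 10, 5, 1)$t, 0)

  # raw-data oracle: construct samples matching the summaries exactly
  mk <- function(n, m, s) { x <- scale(rnorm(n)); as.numeric(x * s + m) }
  set.seed(7)
  x1 <- mk(30, 1.2, 0.8); x2 <- mk(25, 0.7, 1.1)
  byhand <- two_sample_t(30, mean(x1), sd(x1), 25, mean(x2), sd(x2))
  tt <- stats::t.test(x1, x2, var.equal = TRUE)
  expect_equal(byhand$t, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(byhand$p, tt$p.value, tolerance = 1e-10)

  expect_error(two_sample_t(5, 1, 0, 5, 1, 0), "pooled")
})

test_that("median split sends ties to the low group and needs variation", {
  s <- c(1, 2, 2, 3, 4)
  expect_equal(as.character(median_split(s)),
               c("low", "low", "low", "high", "high"))
  expect_error(median_split(rep(3, 6)), "equal")
})

test_that("test/validation comparison returns exact correlations", {
  mt <- make_templates_on_mask <- function() {
    mask <- array(1, c(8, 8, 4))
    t1 <- array(0, dim(mask)); t1[1:3, 1:3, 1:2] <- 1
    list(mask = mask, templates = list(t1))
  }
  mt <- mt()
  v <- sum(mt$mask)
  set.seed(8)
  z <- matrix(rnorm(2 * v), 2, v)
  same <- compare_test_validation(z, z, mt$templates, mt$mask)
  expect_equal(unname(same$r), c(1, 1))
  neg <- compare_test_validation(z, -z, mt$templates, mt$mask)
  expect_equal(unname(neg$r), c(-1, -1))
  expect_error(compare_test_validation(z, z[, 1:10], mt$templates, mt$mask),
               "different shapes")
})
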