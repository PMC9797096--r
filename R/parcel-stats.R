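# Parcel-level statistics: mean-Z extraction per labeled region, the
# random-intercept mixed model Z ~ hemisphere + fc_map * region +
# (1 | participant) with type-III Satterthwaite ANOVA, effect contrasts and
# pairwise z-ratios via estimated marginal means, the summed pairwise
# z-ratio subregion ranking, the fear-group (median split) analysis, and
# the test/validation map comparison.

#' Extract per-region mean Z values from a subject map
#'
#' Averages a subject's component Z maps over the voxels of every label in
#' an integer atlas, split by the hemisphere tag of the lookup table.
#'
#' @param fc_map a `subject_fc_map` (or d x V matrix with attribute voxels).
#' @param atlas 3D integer label array on the same grid.
#' @param lookup data.frame with columns `label`, `name`, `hemisphere`.
#' @param participant participant identifier for the output rows.
#' @return data.frame (long): participant, hemisphere, region, component,
#'   z. Labels present in the atlas but absent from the lookup error;
#'   lookup labels with no voxels inside the map are omitted with a warning.
#' @export
extract_parcel_z <- function(fc_map, atlas, lookup, participant = NA) {
  stopifnot(!is.null(fc_map$voxels))
  labs_here <- atlas[fc_map$voxels]
  present <- setdiff(unique(labs_here), 0)
  missing <- setdiff(present, lookup$label)
  if (length(missing) > 0)
    stopf("atlas labels absent from lookup table: %s",
          paste(missing, collapse = ", "))
  d <- nrow(fc_map$z)
  rows <- list()
  empties <- character(0)
  for (i in seq_len(nrow(lookup))) {
    lab <- lookup$label[i]
    sel <- which(labs_here == lab)
    if (length(sel) == 0L) {
      empties <- c(empties, as.character(lab))
      next
    }
    for (k in seq_len(d)) {
      rows[[length(rows) + 1L]] <- data.frame(
        participant = participant, hemisphere = lookup$hemisphere[i],
        region = lookup$name[i], component = paste0("IC", k),
        z = mean(fc_map$z[k, sel]), stringsAsFactors = FALSE)
    }
  }
  if (length(empties) > 0)
    warnf("labels with no in-map voxels omitted: %s",
          paste(empties, collapse = ", "))
  do.call(rbind, rows)
}

# Ensure the factor columns of a parcel Z table use sum-to-zero contrasts so
# type-III tests are well defined.
.prep_table <- function(table, extra = character(0)) {
  for (col in c("hemisphere", "region", "component", "participant", extra)) {
    if (!col %in% names(table)) stopf("table lacks column '%s'", col)
    table[[col]] <- factor(table[[col]])
    if (col != "participant")
      stats::contrasts(table[[col]]) <- stats::contr.sum(nlevels(table[[col]]))
  }
  table
}

#' Fit the random-intercept mixed model to a parcel Z table
#'
#' REML fit of `z ~ hemisphere + component * region + (1 | participant)`
#' with sum-to-zero factor coding, via `lmerTest::lmer` (extra fixed terms,
#' e.g. covariates and their interactions, can be prepended).
#'
#' @param table long data.frame with columns participant, hemisphere,
#'   region, component, z (one row per cell).
#' @param extra_fixed optional character vector of extra fixed-effect terms
#'   (columns of `table`), e.g. `c("gender", "group * component * region")`.
#' @return a fitted `lmerModLmerTest` object.
#' @export
fit_lmm <- function(table, extra_fixed = character(0)) {
  extra_cols <- unique(unlist(strsplit(extra_fixed, "[^[:alnum:]_.]+")))
  extra_cols <- extra_cols[extra_cols %in% names(table)]
  table <- .prep_table(table, extra_cols)
  for (col in c("hemisphere", "region", "component"))
    if (nlevels(table[[col]]) < 2)
      stopf("factor '%s' needs >= 2 levels", col)
  if (min(table(table$participant)) < 2)
    stopf("every participant needs >= 2 observations")
  rhs <- paste(c(extra_fixed, "hemisphere", "component * region",
                 "(1 | participant)"), collapse = " + ")
  fit <- lmerTest::lmer(stats::as.formula(paste("z ~", rhs)), data = table,
                        REML = TRUE,
                        control = lme4::lmerControl(check.conv.singular = "ignore"))
  fit
}

#' Type-III ANOVA table with Satterthwaite degrees of freedom
#'
#' @param fit a fit from [fit_lmm()].
#' @return data.frame: term, sum_sq, mean_sq, num_df, den_df, f, p.
#' @export
anova_type3 <- function(fit) {
  a <- stats::anova(fit, type = 3)
  data.frame(term = rownames(a), sum_sq = a$`Sum Sq`, mean_sq = a$`Mean Sq`,
             num_df = a$NumDF, den_df = a$DenDF, f = a$`F value`,
             p = a$`Pr(>F)`, row.names = NULL, stringsAsFactors = FALSE)
}

#' Effect contrasts of each component map against the mean of the others
#'
#' For every region and component map m, estimates
#' `EMM(m) - mean(EMM(other maps))` on the estimated marginal means, with an
#' asymptotic-normal z-ratio and Bonferroni adjustment over all contrasts in
#' the table (the family is the whole table).
#'
#' @param fit a fit from [fit_lmm()].
#' @param by factor defining the table rows (default "region").
#' @return data.frame: region, component, estimate, se, z_ratio, p, p_adj.
#' @export
emm_contrasts <- function(fit, by = "region") {
  em <- emmeans::emmeans(fit, stats::as.formula(paste("~ component |", by)),
                         lmer.df = "asymptotic")
  s <- summary(emmeans::contrast(em, "del.eff", adjust = "none"))
  m <- nrow(s)
  if (m == 0L) stopf("empty contrast family")
  out <- data.frame(region = s[[by]],
                    component = sub(" effect$", "", s$contrast),
                    estimate = s$estimate, se = s$SE, z_ratio = s$z.ratio,
                    p = s$p.value, stringsAsFactors = FALSE)
  out$p_adj <- pmin(1, out$p * m)
  out
}

#' Pairwise region z-ratio matrices per component map
#'
#' All pairwise region contrasts of the estimated marginal means within each
#' component map, as antisymmetric matrices of asymptotic z-ratios
#' (`z[i, j]` compares region i minus region j).
#'
#' @param fit a fit from [fit_lmm()].
#' @return named list (one antisymmetric R x R matrix per component).
#' @export
pairwise_z_matrices <- function(fit) {
  em <- emmeans::emmeans(fit, ~ region | component, lmer.df = "asymptotic")
  s <- summary(emmeans::contrast(em, "pairwise", adjust = "none"))
  regions <- unique(unlist(strsplit(as.character(s$contrast), " - ")))
  comps <- unique(as.character(s$component))
  out <- lapply(comps, function(cm) {
    zm <- matrix(0, length(regions), length(regions),
                 dimnames = list(regions, regions))
    sc <- s[s$component == cm, ]
    pr <- strsplit(as.character(sc$contrast), " - ")
    for (i in seq_len(nrow(sc))) {
      a <- pr[[i]][1]; b <- pr[[i]][2]
      zm[a, b] <- sc$z.ratio[i]
      zm[b, a] <- -sc$z.ratio[i]
    }
    zm
  })
  names(out) <- comps
  out
}

#' Rank subregions by summed pairwise z-ratio
#'
#' Sums each subregion's row of the antisymmetric pairwise z-ratio matrix,
#' retains strictly positive sums, and ranks them in descending order. By
#' antisymmetry the sums over all subregions total zero.
#'
#' @param zmat antisymmetric matrix of pairwise z-ratios (zero diagonal).
#' @param tol antisymmetry tolerance.
#' @return data.frame: subregion, summed_z_ratio, rank (possibly 0 rows);
#'   attribute `sums` carries the unthresholded sums.
#' @export
rank_nuclei <- function(zmat, tol = 1e-8) {
  zmat <- as.matrix(zmat)
  if (max(abs(zmat + t(zmat))) > tol)
    stopf("pairwise matrix is not antisymmetric (max |z + t(z)| = %.3g)",
          max(abs(zmat + t(zmat))))
  sums <- rowSums(zmat)
  keep <- which(sums > 0)
  ord <- keep[order(sums[keep], decreasing = TRUE)]
  out <- data.frame(
    subregion = if (!is.null(rownames(zmat))) rownames(zmat)[ord] else ord,
    summed_z_ratio = sums[ord],
    rank = seq_along(ord), row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "sums") <- sums
  out
}

#' Rankings of subregion contributions for every component map
#'
#' @param fit a fit from [fit_lmm()] on the subregion table.
#' @return named list of [rank_nuclei()] tables, one per component.
#' @export
nucleus_rankings <- function(fit) {
  lapply(pairwise_z_matrices(fit), rank_nuclei)
}

#' Two-sample pooled-variance t test from group summaries
#'
#' @param n1,mean1,sd1,n2,mean2,sd2 per-group size, mean and SD.
#' @return list: t, df (= n1 + n2 - 2), p (two-sided).
#' @export
two_sample_t <- function(n1, mean1, sd1, n2, mean2, sd2) {
  stopifnot(n1 >= 2, n2 >= 2)
  if (sd1 < 0 || sd2 < 0) stopf("SDs must be nonnegative")
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  if (sp2 == 0) stopf("zero pooled variance")
  t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Split participants into low/high groups at the median score
#'
#' Ties at the median go to the LOW group.
#'
#' @param scores named or ordered numeric vector (one per participant).
#' @return factor with levels low, high.
#' @export
median_split <- function(scores) {
  if (length(unique(scores)) < 2L)
    stopf("cannot median-split: all scores are equal")
  med <- stats::median(scores)
  factor(ifelse(scores > med, "high", "low"), levels = c("low", "high"))
}

#' Fear-group analysis of subregion co-activity
#'
#' Median-splits the fear scores into low/high groups, fits the extended
#' mixed model `z ~ gender (+ age_band) + hemisphere +
#' group * component * region + (1 | participant)` (age is dropped when
#' nonsignificant), and — when the Group x region interaction is significant
#' at `alpha` — runs low-vs-high posthoc contrasts per subregion and per
#' (subregion, component) cell, each table Bonferroni-adjusted within
#' itself.
#'
#' @param table subregion parcel Z table (participant, hemisphere, region,
#'   component, z).
#' @param covariates data.frame with participant_id, age_band, gender,
#'   fear_score.
#' @param alpha significance level for the interaction gate.
#' @return list: `groups` (participant, score, group), `anova`,
#'   `age_dropped`, `interaction_p`, `gated` (whether posthoc ran),
#'   `posthoc_by_region`, `posthoc_by_cell`, `passing` (subregions with a
#'   Bonferroni-significant group difference in either table).
#' @export
fear_group_analysis <- function(table, covariates, alpha = 0.05) {
  if (!all(table$participant %in% covariates$participant_id))
    stopf("missing covariates for some participants")
  idx <- match(table$participant, covariates$participant_id)
  grp_by_part <- median_split(covariates$fear_score)
  table$group <- grp_by_part[idx]
  table$gender <- covariates$gender[idx]
  table$age_band <- covariates$age_band[idx]

  fixed <- c("gender", "age_band", "group * component * region")
  # drop factors that cannot be estimated (single level in this cohort)
  if (length(unique(table$gender)) < 2) fixed <- setdiff(fixed, "gender")
  if (length(unique(table$age_band)) < 2) fixed <- setdiff(fixed, "age_band")
  fit <- fit_lmm(table, extra_fixed = fixed)
  an <- anova_type3(fit)
  age_dropped <- FALSE
  if ("age_band" %in% an$term && an$p[an$term == "age_band"] >= alpha) {
    age_dropped <- TRUE
    fit <- fit_lmm(table, extra_fixed = setdiff(fixed, "age_band"))
    an <- anova_type3(fit)
  }
  ip <- an$p[an$term == "group:region"]
  gated <- length(ip) == 1 && is.finite(ip) && ip < alpha

  posthoc_region <- posthoc_cell <- NULL
  passing <- character(0)
  if (gated) {
    em_r <- emmeans::emmeans(fit, ~ group | region, lmer.df = "asymptotic")
    s_r <- summary(emmeans::contrast(em_r, "pairwise", adjust = "none"))
    posthoc_region <- data.frame(region = s_r$region, estimate = s_r$estimate,
                                 se = s_r$SE, z_ratio = s_r$z.ratio,
                                 p = s_r$p.value, stringsAsFactors = FALSE)
    posthoc_region$p_adj <- pmin(1, posthoc_region$p * nrow(posthoc_region))
    em_c <- emmeans::emmeans(fit, ~ group | region * component,
                             lmer.df = "asymptotic")
    s_c <- summary(emmeans::contrast(em_c, "pairwise", adjust = "none"))
    posthoc_cell <- data.frame(region = s_c$region, component = s_c$component,
                               estimate = s_c$estimate, se = s_c$SE,
                               z_ratio = s_c$z.ratio, p = s_c$p.value,
                               stringsAsFactors = FALSE)
    posthoc_cell$p_adj <- pmin(1, posthoc_cell$p * nrow(posthoc_cell))
    passing <- union(
      as.character(posthoc_region$region[posthoc_region$p_adj < alpha]),
      as.character(posthoc_cell$region[posthoc_cell$p_adj < alpha]))
  }
  list(groups = data.frame(participant = covariates$participant_id,
                           score = covariates$fear_score,
                           group = grp_by_part, stringsAsFactors = FALSE),
       anova = an, age_dropped = age_dropped,
       interaction_p = if (length(ip) == 1) ip else NA_real_,
       gated = gated, posthoc_by_region = posthoc_region,
       posthoc_by_cell = posthoc_cell, passing = passing)
}

#' Compare test- and validation-set group maps
#'
#' Per-component Pearson correlation over brain-mask voxels between two sets
#' of group maps (validation maps computed from the test-set seed
#' components), plus a re-match of the validation maps against the
#' templates.
#'
#' @param maps_test,maps_val `group_fc_map` objects (or d x V matrices) on
#'   the same grid and component indexing.
#' @param templates list of binary template arrays.
#' @param brain_mask 3D binary array.
#' @param r_star detection threshold passed to [assign_networks()].
#' @return list: `r` (per-component correlation), `match_val` (validation
#'   match matrix), `assignment_val`.
#' @export
compare_test_validation <- function(maps_test, maps_val, templates,
                                    brain_mask, r_star = 0.4) {
  zt <- if (inherits(maps_test, "group_fc_map")) maps_test$z else as.matrix(maps_test)
  zv <- if (inherits(maps_val, "group_fc_map")) maps_val$z else as.matrix(maps_val)
  if (!all(dim(zt) == dim(zv)))
    stopf("test and validation maps have different shapes")
  r <- vapply(seq_len(nrow(zt)), function(k) stats::cor(zt[k, ], zv[k, ]),
              numeric(1))
  names(r) <- paste0("IC", seq_len(nrow(zt)))
  mv <- correlate_with_templates(maps_val, templates, brain_mask)
  list(r = r, match_val = mv, assignment_val = assign_networks(mv, r_star))
}
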