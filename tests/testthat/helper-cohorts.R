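# Shared fixtures: small cohorts are built in code at test time.

# A reduced cohort for fast unit tests (not the reference conditions).
small_config <- function(...) {
  synthetic_config(n_subjects = 6, n_sessions_per_subject = 2,
                   n_timepoints = 120, ...)
}

# Preprocess every session of a cohort and split seed/brain matrices.
prep_cohort <- function(cohort, sessions = NULL) {
  ns <- length(cohort$subjects[[1]])
  if (is.null(sessions)) sessions <- seq_len(ns)
  prep <- lapply(cohort$subjects, function(ss)
    lapply(ss[sessions], srica:::preprocess_session,
           seed_mask = cohort$seed_mask, brain_mask = cohort$brain_mask))
  list(seed = lapply(prep, function(p) lapply(p, `[[`, "seed")),
       brain = lapply(prep, function(p) lapply(p, `[[`, "brain")))
}

# True per-voxel seed loading pattern (V x K) for a cohort.
true_seed_pattern <- function(cohort) {
  spec <- cohort$config$seed_region_spec
  idx <- which(cohort$seed_mask != 0)
  nm <- spec$name[match(cohort$seed_atlas[idx], spec$label)]
  cohort$config$loading_matrix[nm, , drop = FALSE]
}

# True whole-brain coupling pattern (brain-mask voxels x K): the assigned
# template outside the seed, the hemisphere-adjusted subregion loadings
# inside it — i.e. exactly the coupling the generator uses.
true_brain_pattern <- function(cohort) {
  cfg <- cohort$config
  g <- cfg$grid_shape
  spec <- cfg$seed_region_spec
  G <- vapply(cohort$truth$template_assignment, function(a)
    as.numeric(cohort$templates[[a]]), numeric(prod(g)))
  seed_idx <- which(cohort$seed_mask != 0)
  nm <- spec$name[match(cohort$seed_atlas[seed_idx], spec$label)]
  hemi <- spec$hemisphere[match(cohort$seed_atlas[seed_idx], spec$label)]
  G[seed_idx, ] <- cfg$loading_matrix[nm, , drop = FALSE] *
    (1 + cfg$hemisphere_offset * (hemi == "R"))
  G[which(cohort$brain_mask != 0), , drop = FALSE]
}

# Greedy match of recovered maps to true patterns; returns |r| per truth col.
match_abs_cor <- function(maps, truth) {
  cc <- abs(stats::cor(t(maps), truth))
  apply(cc, 2L, max)
}
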