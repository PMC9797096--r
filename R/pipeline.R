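# End-to-end orchestration: configuration, QC filtering, the dimension
# sweep, and the full pipeline run with deterministic stage seeds and
# TSV/JSON outputs.

#' Pipeline configuration
#'
#' Validates and normalizes the knobs of a full pipeline run. Either a
#' `synthetic` block (a [synthetic_config()]) or a `data_dir` with an
#' on-disk cohort must be supplied.
#'
#' @param d_min,d_max model-order sweep bounds (1 <= d_min <= d_max).
#' @param r_star network-detection correlation threshold in (0, 1).
#' @param n_permutations sign-flip permutations for the final group maps.
#' @param rng_seed root seed; stage seeds are derived at fixed offsets.
#' @param synthetic optional [synthetic_config()] used to simulate data.
#' @param data_dir optional directory with a cohort written by [make_cohort()].
#' @param test_sessions,validation_sessions session indices of the
#'   test/validation split (validation may be empty).
#' @param qc_flags manifest flag letters that exclude a participant.
#' @param out_dir optional output directory for result tables.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(d_min = 1, d_max = 10, r_star = 0.4,
                            n_permutations = 0, rng_seed = 42,
                            synthetic = NULL, data_dir = NULL,
                            test_sessions = 1, validation_sessions = 2,
                            qc_flags = c("A", "B", "C", "D"),
                            out_dir = NULL) {
  if (d_min < 1 || d_max < d_min)
    stopf("need 1 <= d_min <= d_max (got %s..%s)", d_min, d_max)
  if (r_star <= 0 || r_star >= 1) stopf("r_star must lie in (0, 1)")
  if (is.null(synthetic) && is.null(data_dir))
    stopf("either a synthetic config or a data_dir is required")
  if (!is.null(data_dir) && !dir.exists(data_dir))
    stopf("data_dir '%s' does not exist", data_dir)
  structure(list(d_min = as.integer(d_min), d_max = as.integer(d_max),
                 r_star = r_star, n_permutations = as.integer(n_permutations),
                 rng_seed = as.integer(rng_seed), synthetic = synthetic,
                 data_dir = data_dir,
                 test_sessions = as.integer(test_sessions),
                 validation_sessions = as.integer(validation_sessions),
                 qc_flags = qc_flags, out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys are [pipeline_config()] arguments (a
#'   `synthetic` mapping is passed to [synthetic_config()]).
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$synthetic)) y$synthetic <- do.call(synthetic_config, y$synthetic)
  do.call(pipeline_config, y)
}

#' Filter a participant manifest on QC flags
#'
#' Removes rows whose `qc_flags` entry contains any excluding flag letter;
#' input, excluded and retained counts are attached as attribute `counts`.
#'
#' @param manifest data.frame with unique `participant_id` and a `qc_flags`
#'   character column ("" or e.g. "A;C").
#' @param flags flag letters that exclude a participant.
#' @return the retained manifest (warns when empty).
#' @export
apply_qc_filter <- function(manifest, flags = c("A", "B", "C", "D")) {
  if (anyDuplicated(manifest$participant_id))
    stopf("duplicate participant ids in manifest")
  fl <- manifest$qc_flags
  if (is.null(fl)) fl <- rep("", nrow(manifest))
  fl[is.na(fl)] <- ""
  bad <- vapply(strsplit(fl, "[;, ]+"), function(f) any(f %in% flags),
                logical(1))
  retained <- manifest[!bad, , drop = FALSE]
  if (nrow(retained) == 0L)
    warnf("QC filter removed all %d participants", nrow(manifest))
  attr(retained, "counts") <- c(input = nrow(manifest),
                                excluded = sum(bad),
                                retained = nrow(retained))
  retained
}

# Preprocess one session: extract seed and brain matrices, highpass both
# (nuisance regressors, when given, are filtered with the same filter and
# regressed out after filtering).
preprocess_session <- function(series, seed_mask, brain_mask,
                               nuisance = NULL, cutoff = 2000) {
  seed_mm <- extract_masked_matrix(series, seed_mask)
  brain_mm <- extract_masked_matrix(series, brain_mask)
  seed_mm <- highpass_filter(seed_mm, series$tr, cutoff)
  brain_mm <- highpass_filter(brain_mm, series$tr, cutoff)
  if (!is.null(nuisance)) {
    reg <- highpass_filter(as.matrix(nuisance), series$tr, cutoff)
    seed_mm <- regress_nuisance(seed_mm, reg)
    brain_mm <- regress_nuisance(brain_mm, reg)
  }
  list(seed = seed_mm, brain = brain_mm)
}

# Dual-regress all subjects at one model order and build the group map.
# seed_mats / brain_mats: list[subject][session].
.dualreg_group <- function(ic, seed_mats, brain_mats, n_permutations = 0,
                           rng_seed = 1) {
  subj_maps <- vector("list", length(seed_mats))
  for (i in seq_along(seed_mats)) {
    per_session <- lapply(seq_along(seed_mats[[i]]), function(s) {
      tc <- stage1_timecourses(seed_mats[[i]][[s]], ic$spatial_maps)
      stage2_subject_maps(brain_mats[[i]][[s]], tc, subject = i, session = s)
    })
    subj_maps[[i]] <- average_sessions(per_session)
  }
  list(group = group_map(subj_maps, n_permutations, rng_seed),
       subject_maps = subj_maps)
}

#' Sweep ICA model orders and match each to the reference templates
#'
#' For every dimension in `d_range`: group ICA on the concatenated seed
#' data, skewness orientation, dual regression to a group whole-brain map,
#' template correlation and network assignment.
#'
#' @param seed_mats,brain_mats nested lists `[[subject]][[session]]` of
#'   preprocessed `masked_matrix` data (seed region / whole brain).
#' @param templates,brain_mask reference templates and correlation domain.
#' @param d_range integer vector of model orders.
#' @param rng_seed base seed (offset per dimension).
#' @param r_star detection threshold.
#' @return named list (by dimension): `ic`, `r`, `assignment`, `group`.
#' @export
sweep_dimensions <- function(seed_mats, brain_mats, templates, brain_mask,
                             d_range, rng_seed = 1, r_star = 0.4) {
  flat_seed <- unlist(seed_mats, recursive = FALSE)
  gm <- concat_subjects(flat_seed)
  out <- list()
  for (d in d_range) {
    out[[as.character(d)]] <- tryCatch({
      ic <- orient_components(group_spatial_ica(gm, d, rng_seed + d))
      dr <- .dualreg_group(ic, seed_mats, brain_mats)
      r <- correlate_with_templates(dr$group, templates, brain_mask)
      list(ic = ic, r = r, assignment = assign_networks(r, r_star),
           group = dr$group)
    }, error = function(e) {
      # a model order can legitimately fail (e.g. oscillating ICA rotation
      # when the order is badly misspecified); record and keep sweeping
      warnf("dimension %d skipped: %s", d, conditionMessage(e))
      list(error = conditionMessage(e))
    })
  }
  out
}

#' Run the full analysis pipeline
#'
#' Simulates or loads a cohort, applies QC filtering and preprocessing,
#' sweeps ICA model orders on the test sessions, selects the dimension,
#' computes final subject and group maps (with optional permutation
#' inference), extracts whole-brain parcel and seed-subregion tables, fits
#' the mixed models (type-III ANOVA, effect contrasts, subregion rankings),
#' runs the fear-group analysis, and compares test against validation
#' sessions. All outputs are deterministic given `rng_seed`; result tables
#' are written to `out_dir` when set, along with a run manifest.
#'
#' @param config a [pipeline_config()].
#' @param cohort optional pre-built `synthetic_cohort` (overrides simulate).
#' @return list of class `pipeline_result` with all stage outputs.
#' @export
run_pipeline <- function(config, cohort = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$rng_seed

  # --- data -----------------------------------------------------------
  if (is.null(cohort)) {
    cohort <- if (!is.null(config$synthetic)) simulate_cohort(config$synthetic)
    else load_cohort(config$data_dir)
  }
  manifest <- cohort$covariates
  if (!is.null(manifest$qc_flags)) {
    manifest <- apply_qc_filter(manifest, config$qc_flags)
    keep <- match(manifest$participant_id, cohort$covariates$participant_id)
    cohort$subjects <- cohort$subjects[keep]
    cohort$covariates <- cohort$covariates[keep, , drop = FALSE]
    if (length(cohort$subjects) == 0L)
      stopf("no participants left after QC filtering")
  }
  qc_counts <- attr(manifest, "counts")

  n_sessions <- length(cohort$subjects[[1]])
  test_s <- intersect(config$test_sessions, seq_len(n_sessions))
  val_s <- intersect(config$validation_sessions, seq_len(n_sessions))
  if (length(test_s) == 0L) stopf("no test sessions available")

  # --- preprocessing --------------------------------------------------
  prep <- lapply(cohort$subjects, function(sess)
    lapply(sess, preprocess_session, seed_mask = cohort$seed_mask,
           brain_mask = cohort$brain_mask))
  pick <- function(which_s, what) lapply(prep, function(p)
    lapply(p[which_s], `[[`, what))
  seed_test <- pick(test_s, "seed"); brain_test <- pick(test_s, "brain")

  # --- dimension sweep and selection ---------------------------------
  sweep <- sweep_dimensions(seed_test, brain_test, cohort$templates,
                            cohort$brain_mask, config$d_min:config$d_max,
                            rng_seed = seed + 100L, r_star = config$r_star)
  selection <- select_dimension(sweep)
  if (selection$status != "ok") {
    return(structure(list(selection = selection, sweep = sweep,
                          qc_counts = qc_counts, config = config),
                     class = "pipeline_result"))
  }
  chosen <- as.character(selection$chosen_d)
  ic <- sweep[[chosen]]$ic
  final <- .dualreg_group(ic, seed_test, brain_test,
                          n_permutations = config$n_permutations,
                          rng_seed = seed + 200L)

  # --- parcel tables --------------------------------------------------
  ids <- cohort$covariates$participant_id
  seed_masked <- lapply(seq_along(ids), function(i) {
    per_session <- lapply(test_s, function(s) {
      tc <- stage1_timecourses(seed_test[[i]][[match(s, test_s)]], ic$spatial_maps)
      stage2_subject_maps(seed_test[[i]][[match(s, test_s)]], tc,
                          subject = ids[i], session = s)
    })
    average_sessions(per_session)
  })
  parcel_tab <- do.call(rbind, lapply(seq_along(ids), function(i)
    extract_parcel_z(final$subject_maps[[i]], cohort$parcel_atlas,
                     cohort$parcel_lookup, participant = ids[i])))
  nucleus_tab <- do.call(rbind, lapply(seq_along(ids), function(i)
    extract_parcel_z(seed_masked[[i]], cohort$seed_atlas,
                     cohort$seed_lookup, participant = ids[i])))

  # --- mixed models ---------------------------------------------------
  fit_parcel <- fit_lmm(parcel_tab)
  anova_parcel <- anova_type3(fit_parcel)
  ip <- anova_parcel$p[anova_parcel$term == "component:region"]
  contrasts_parcel <- if (length(ip) == 1 && is.finite(ip) && ip < 0.05)
    emm_contrasts(fit_parcel) else NULL

  fit_nuc <- fit_lmm(nucleus_tab)
  anova_nuc <- anova_type3(fit_nuc)
  rankings <- nucleus_rankings(fit_nuc)

  fear <- fear_group_analysis(nucleus_tab, cohort$covariates)

  # --- validation -----------------------------------------------------
  validation <- NULL
  if (length(val_s) > 0) {
    seed_val <- pick(val_s, "seed"); brain_val <- pick(val_s, "brain")
    val <- .dualreg_group(ic, seed_val, brain_val)
    validation <- compare_test_validation(final$group, val$group,
                                          cohort$templates, cohort$brain_mask,
                                          config$r_star)
    validation$group_val <- val$group
  }

  result <- structure(list(
    selection = selection, sweep_table = selection$sweep_table,
    assignment = selection$assignment, ic = ic,
    group = final$group, subject_maps = final$subject_maps,
    parcel_table = parcel_tab, nucleus_table = nucleus_tab,
    anova_parcel = anova_parcel, contrasts_parcel = contrasts_parcel,
    anova_nuclei = anova_nuc, rankings = rankings,
    fear = fear, validation = validation,
    qc_counts = qc_counts, truth = cohort$truth, config = config),
    class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_outputs(result, config$out_dir)
  result
}

# Write the result tables (TSV + JSON) and a run manifest.
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wtsv <- function(df, name) {
    if (!is.null(df))
      utils::write.table(df, file.path(out_dir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
  }
  wtsv(result$sweep_table, "sweep_table.tsv")
  wtsv(result$assignment, "network_assignment.tsv")
  wtsv(result$parcel_table, "parcel_z.tsv")
  wtsv(result$nucleus_table, "nucleus_z.tsv")
  wtsv(result$anova_parcel, "anova_parcel.tsv")
  wtsv(result$contrasts_parcel, "contrasts_parcel.tsv")
  wtsv(result$anova_nuclei, "anova_nuclei.tsv")
  for (nm in names(result$rankings))
    wtsv(result$rankings[[nm]], sprintf("ranking_%s.tsv", nm))
  jsonlite::write_json(
    list(anova_parcel = result$anova_parcel,
         anova_nuclei = result$anova_nuclei,
         fear_anova = result$fear$anova,
         fear_passing = result$fear$passing,
         validation_r = result$validation$r),
    file.path(out_dir, "stats.json"), auto_unbox = TRUE, digits = NA)
  cfg <- result$config
  manifest <- list(
    package_version = as.character(utils::packageVersion("srica")),
    rng_seed = cfg$rng_seed,
    config_hash = rlang::hash(cfg),
    chosen_d = result$selection$chosen_d,
    n_subjects = length(result$subject_maps),
    n_permutations = cfg$n_permutations,
    z_clip = Z_CLIP,
    qc_counts = as.list(qc <- if (is.null(result$qc_counts))
      c(input = NA, excluded = NA, retained = NA) else result$qc_counts))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Load a cohort written by [make_cohort()]
#'
#' @param dir cohort root directory.
#' @return a `synthetic_cohort`-shaped list (without ground truth unless
#'   `truth.json` is present).
#' @export
load_cohort <- function(dir) {
  subs <- sort(list.dirs(dir, recursive = FALSE))
  subs <- subs[grepl("sub-", basename(subs))]
  if (length(subs) == 0L) stopf("no sub-* directories in '%s'", dir)
  subjects <- lapply(subs, function(sd) {
    sess <- sort(list.dirs(sd, recursive = FALSE))
    lapply(sess, function(ss) read_series(file.path(ss, "func.nii.gz")))
  })
  rtsv <- function(f) utils::read.table(file.path(dir, f), header = TRUE,
                                        sep = "\t", stringsAsFactors = FALSE)
  tfiles <- sort(list.files(dir, pattern = "^template-", full.names = TRUE))
  truth_path <- file.path(dir, "truth.json")
  structure(list(
    subjects = subjects,
    seed_mask = read_volume(file.path(dir, "seed_mask.nii.gz")),
    seed_atlas = read_volume(file.path(dir, "seed_atlas.nii.gz")),
    parcel_atlas = read_volume(file.path(dir, "parcel_atlas.nii.gz")),
    brain_mask = read_volume(file.path(dir, "brain_mask.nii.gz")),
    templates = lapply(tfiles, read_volume),
    seed_lookup = rtsv("seed_lookup.tsv"),
    parcel_lookup = rtsv("parcel_lookup.tsv"),
    covariates = rtsv("participants.tsv"),
    truth = if (file.exists(truth_path)) jsonlite::read_json(truth_path,
                                                             simplifyVector = TRUE)
    else NULL),
    class = "synthetic_cohort")
}
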