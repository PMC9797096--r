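# Synthetic multi-subject 4D cohorts with known ground truth.
#
# The generator embeds K latent network time-courses that drive (a) spatial
# clusters inside a labeled seed region, cutting across subregion labels, and
# (b) disjoint whole-brain template networks, on top of AR(1) noise, a
# hemisphere offset, between-participant variability, and an optional
# covariate-dependent coupling boost in one designated subregion.

NUCLEUS_TABLE <- data.frame(
  name = c("AB", "Ba", "La", "PL", "Ce", "Me", "AAA", "Co", "CAT"),
  full_name = c("Accessory Basal nucleus", "Basal nucleus", "Lateral nucleus",
                "Paralaminar nucleus", "Central nucleus", "Medial nucleus",
                "Anterior Amygdaloid Area", "Cortical nucleus",
                "CorticoAmygdaloid Transition area"),
  division = c("LB", "LB", "LB", "LB", "CM", "CM", "SF", "SF", "SF"),
  stringsAsFactors = FALSE)

#' Default subregion layout for the synthetic seed region
#'
#' Nine subregion labels per hemisphere (mirroring an amygdala nucleus
#' parcellation), each a small rectangular block; left and right hemisphere
#' blocks sit in opposite x halves of the grid.
#'
#' @param grid_shape integer length-3 grid dimensions.
#' @return data.frame with one row per (subregion, hemisphere): integer
#'   `label`, `name`, `hemisphere`, `division`, and inclusive voxel extents
#'   `x0,x1,y0,y1,z0,z1`.
#' @export
default_seed_region_spec <- function(grid_shape = c(24, 24, 12)) {
  bw <- 3; bh <- 3; bd <- 2                # block extents per subregion
  if (grid_shape[1] < 2 * 3 * bw + 4 || grid_shape[2] < 3 * bh + 2 ||
      grid_shape[3] < bd + 2)
    stopf("grid %s too small for the default 9-subregion layout",
          paste(grid_shape, collapse = "x"))
  y0 <- floor((grid_shape[2] - 3 * bh) / 2) + 1
  z0 <- floor((grid_shape[3] - bd) / 2) + 1
  rows <- list()
  lab <- 0L
  for (hemi in c("L", "R")) {
    xs <- if (hemi == "L") 2L else grid_shape[1] - 3L * bw
    for (i in seq_len(9)) {
      lab <- lab + 1L
      cx <- (i - 1L) %% 3L
      cy <- (i - 1L) %/% 3L
      rows[[lab]] <- data.frame(
        label = lab, name = NUCLEUS_TABLE$name[i], hemisphere = hemi,
        division = NUCLEUS_TABLE$division[i],
        x0 = xs + cx * bw, x1 = xs + cx * bw + bw - 1L,
        y0 = y0 + cy * bh, y1 = y0 + cy * bh + bh - 1L,
        z0 = z0, z1 = z0 + bd - 1L, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Default subregion-by-network coupling weights
#'
#' Each of the three networks is anchored in a disjoint two-subregion
#' cluster with graded weights, so that every embedded cluster cuts across
#' two subregion labels while the latent sources stay spatially disjoint and
#' sparse inside the seed (three subregions stay unloaded), keeping them
#' identifiable by ICA.
#'
#' @param n_networks number of latent networks (1..3 use the built-in
#'   clusters; more networks error).
#' @return 9 x K matrix, rownames are subregion names.
#' @export
default_loading_matrix <- function(n_networks = 3) {
  if (n_networks > 3)
    stopf("default loading matrix defines at most 3 networks; supply your own")
  L <- matrix(0, 9, 3, dimnames = list(NUCLEUS_TABLE$name, NULL))
  L[c("Co", "AAA"), 1] <- c(1.0, 0.6)   # ventral-attention-like
  L[c("CAT", "PL"), 2] <- c(1.0, 0.7)   # somatomotor-like
  L[c("Me", "AB"), 3] <- c(1.0, 0.5)    # default-mode-like
  L[, seq_len(n_networks), drop = FALSE]
}

#' Configuration of a synthetic cohort
#'
#' Defaults define the reference simulation conditions used throughout the
#' package's tests: 20 participants, 2 sessions each, 200 time points at
#' TR 1 s, 3 latent networks on a 24 x 24 x 12 grid, voxel SNR 1, AR(1)
#' noise (phi 0.3), 10% between-participant coupling gain SD, +10% right-
#' hemisphere coupling offset, and a fear-score coupling boost of 5% per
#' score unit in the Co subregion on network 1.
#'
#' @param grid_shape 3 positive integers (voxels).
#' @param n_subjects,n_sessions_per_subject,n_timepoints cohort sizes.
#' @param tr_seconds repetition time (s).
#' @param n_networks number of embedded latent networks (K_true).
#' @param n_templates number of reference templates generated (>= K_true).
#' @param seed_region_spec data.frame as from [default_seed_region_spec()].
#' @param loading_matrix subregion x network coupling weights (rows may be
#'   all-zero: an unloaded subregion is legal).
#' @param network_snr signal amplitude divided by noise SD (per voxel).
#' @param ar1_coef lag-1 autoregressive coefficient of the noise, in [0, 1).
#' @param subject_sd SD of the between-participant effect (enters both as a
#'   DC offset and as a multiplicative coupling gain `1 + b`).
#' @param hemisphere_offset fractional coupling increase in the right
#'   hemisphere seed subregions.
#' @param fear_effect list(label, network, slope): multiplicative coupling
#'   boost `1 + slope * (score - median)` applied to the designated
#'   subregion on the designated network.
#' @param fear_means,fear_sds per-group fear score distribution parameters.
#' @param rng_seed integer master seed; all cohort randomness derives from it.
#' @return validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(grid_shape = c(24, 24, 12),
                             n_subjects = 20,
                             n_sessions_per_subject = 2,
                             n_timepoints = 200,
                             tr_seconds = 1,
                             n_networks = 3,
                             n_templates = 7,
                             seed_region_spec = default_seed_region_spec(grid_shape),
                             loading_matrix = default_loading_matrix(n_networks),
                             network_snr = 1,
                             ar1_coef = 0.3,
                             subject_sd = 0.1,
                             hemisphere_offset = 0.1,
                             fear_effect = list(label = "Co", network = 1,
                                                slope = 0.05),
                             fear_means = c(44.0, 55.2),
                             fear_sds = c(4.9, 4.5),
                             rng_seed = 42) {
  cfg <- list(grid_shape = as.integer(grid_shape), n_subjects = as.integer(n_subjects),
              n_sessions_per_subject = as.integer(n_sessions_per_subject),
              n_timepoints = as.integer(n_timepoints), tr_seconds = tr_seconds,
              n_networks = as.integer(n_networks), n_templates = as.integer(n_templates),
              seed_region_spec = seed_region_spec, loading_matrix = as.matrix(loading_matrix),
              network_snr = network_snr, ar1_coef = ar1_coef, subject_sd = subject_sd,
              hemisphere_offset = hemisphere_offset, fear_effect = fear_effect,
              fear_means = fear_means, fear_sds = fear_sds,
              rng_seed = as.integer(rng_seed))
  validate_synthetic_config(cfg)
}

validate_synthetic_config <- function(cfg) {
  stopifnot(length(cfg$grid_shape) == 3, all(cfg$grid_shape > 0),
            cfg$n_subjects >= 1, cfg$n_sessions_per_subject >= 1,
            cfg$n_timepoints >= 4, cfg$tr_seconds > 0, cfg$n_networks >= 1,
            cfg$network_snr > 0, cfg$ar1_coef >= 0, cfg$ar1_coef < 1,
            cfg$subject_sd >= 0)
  if (cfg$n_networks > cfg$n_templates)
    stopf("n_networks (%d) exceeds the number of reference templates (%d)",
          cfg$n_networks, cfg$n_templates)
  spec <- cfg$seed_region_spec
  nseed <- sum((spec$x1 - spec$x0 + 1) * (spec$y1 - spec$y0 + 1) *
                 (spec$z1 - spec$z0 + 1))
  if (prod(cfg$grid_shape) < 8 * nseed)
    stopf("grid has %d voxels; need >= 8x the %d seed voxels",
          prod(cfg$grid_shape), nseed)
  subregions <- unique(spec$name)
  if (nrow(cfg$loading_matrix) != length(subregions))
    stopf("loading_matrix has %d rows but seed_region_spec defines %d subregions",
          nrow(cfg$loading_matrix), length(subregions))
  if (ncol(cfg$loading_matrix) != cfg$n_networks)
    stopf("loading_matrix has %d columns but n_networks is %d",
          ncol(cfg$loading_matrix), cfg$n_networks)
  if (is.null(rownames(cfg$loading_matrix)))
    rownames(cfg$loading_matrix) <- subregions
  fe <- cfg$fear_effect
  if (!is.null(fe) && !fe$label %in% subregions)
    stopf("fear_effect label '%s' is not a seed subregion", fe$label)
  structure(cfg, class = "synthetic_config")
}

#' Generate disjoint binary reference-network templates
#'
#' Places `n_networks` disjoint rectangular blocks inside a brain mask (the
#' full grid minus a one-voxel border), standing in for reference
#' resting-state network maps. Deterministic for a fixed seed.
#'
#' @param n_networks number of templates (>= 1).
#' @param grid_shape 3 integers.
#' @param rng_seed integer seed.
#' @param avoid optional 3D mask of voxels templates must not touch
#'   (e.g. the seed region).
#' @return list with `templates` (list of binary 3D arrays) and
#'   `brain_mask` (binary 3D array).
#' @export
make_reference_templates <- function(n_networks, grid_shape, rng_seed,
                                     avoid = NULL) {
  stopifnot(n_networks >= 1, length(grid_shape) == 3)
  g <- as.integer(grid_shape)
  brain <- array(0L, g)
  brain[2:(g[1] - 1), 2:(g[2] - 1), 2:(g[3] - 1)] <- 1L
  nb <- sum(brain)
  bs <- pmax(2L, as.integer(round(g * 0.3)))   # template block extents
  if (n_networks * prod(bs) >= 0.8 * nb || any(bs >= g - 2L))
    stopf(paste0("grid %s too small to host %d disjoint templates of %s ",
                 "voxels under 80%% brain coverage; need at least %d brain voxels"),
          paste(g, collapse = "x"), n_networks, prod(bs),
          ceiling(n_networks * prod(bs) / 0.8))
  occupied <- array(FALSE, g)
  if (!is.null(avoid)) occupied[avoid != 0] <- TRUE
  templates <- vector("list", n_networks)
  with_seed(rng_seed, {
    for (k in seq_len(n_networks)) {
      placed <- FALSE
      for (try in seq_len(500L)) {
        x0 <- sample.int(g[1] - bs[1] - 1L, 1L) + 1L
        y0 <- sample.int(g[2] - bs[2] - 1L, 1L) + 1L
        z0 <- sample.int(g[3] - bs[3] - 1L, 1L) + 1L
        xs <- x0:(x0 + bs[1] - 1L); ys <- y0:(y0 + bs[2] - 1L)
        zs <- z0:(z0 + bs[3] - 1L)
        if (!any(occupied[xs, ys, zs])) {
          tmpl <- array(0L, g)
          tmpl[xs, ys, zs] <- 1L
          occupied[xs, ys, zs] <- TRUE
          templates[[k]] <- tmpl
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stopf(paste0("could not place %d disjoint templates in grid %s; ",
                     "increase the grid (>= %d free brain voxels required)"),
              n_networks, paste(g, collapse = "x"),
              ceiling(n_networks * prod(bs) / 0.8))
    }
  })
  list(templates = templates, brain_mask = brain)
}

#' Generate fear covariate scores as a two-group mixture
#'
#' Half the participants are drawn from each of two normal distributions
#' (defaults mirror the observed low/high-fear group summaries: means
#' 44.0/55.2, SDs 4.9/4.5); group membership is randomly interleaved across
#' participant indices. Redraws (deterministically) if a half's sample mean
#' falls more than 3 standard errors from its target.
#'
#' @param n_subjects even number of participants.
#' @param group_means,group_sds length-2 numeric vectors.
#' @param rng_seed integer seed.
#' @return numeric vector of `n_subjects` scores with attribute
#'   `generating_group` ("low"/"high").
#' @export
make_fear_scores <- function(n_subjects, group_means = c(44.0, 55.2),
                             group_sds = c(4.9, 4.5), rng_seed = 1) {
  stopifnot(n_subjects %% 2 == 0, n_subjects >= 2)
  if (any(group_sds <= 0)) stopf("group SDs must be positive")
  h <- n_subjects / 2
  with_seed(rng_seed, {
    for (try in seq_len(50L)) {
      lo <- stats::rnorm(h, group_means[1], group_sds[1])
      hi <- stats::rnorm(h, group_means[2], group_sds[2])
      ok <- abs(mean(lo) - group_means[1]) <= 3 * group_sds[1] / sqrt(h) &&
        abs(mean(hi) - group_means[2]) <= 3 * group_sds[2] / sqrt(h)
      if (ok) break
    }
    ord <- sample.int(n_subjects)
    scores <- c(lo, hi)[ord]
    grp <- rep(c("low", "high"), each = h)[ord]
  })
  structure(scores, generating_group = grp)
}

# Latent network time-course: moving-average smoothed white noise, z-scored.
# Band-limited fluctuations resemble resting-state dynamics and keep the
# sources non-Gaussian enough in space for ICA via the spatial maps.
latent_timecourses <- function(tpts, k, width = 5L) {
  x <- matrix(stats::rnorm(tpts * k), tpts, k)
  kern <- rep(1 / width, width)
  x <- apply(x, 2L, function(col)
    stats::filter(c(col[1:(width - 1)], col), kern, sides = 1)[-seq_len(width - 1)])
  x <- scale(x)
  attr(x, "scaled:center") <- NULL
  attr(x, "scaled:scale") <- NULL
  x
}

# AR(1) noise matrix (tpts x nvox) with marginal SD `sd` and lag-1
# autocorrelation `phi`.
ar1_noise <- function(tpts, nvox, sd, phi) {
  innov <- matrix(stats::rnorm(tpts * nvox), tpts, nvox)
  if (phi > 0) {
    innov <- stats::filter(innov, phi, method = "recursive")
    innov <- innov * sqrt(1 - phi^2)       # restore unit marginal variance
  }
  matrix(as.numeric(innov) * sd, tpts, nvox)
}

# Build the 3D integer subregion atlas and binary seed mask from the spec.
build_seed_atlas <- function(spec, grid_shape) {
  atlas <- array(0L, grid_shape)
  for (i in seq_len(nrow(spec))) {
    r <- spec[i, ]
    atlas[r$x0:r$x1, r$y0:r$y1, r$z0:r$z1] <- r$label
  }
  atlas
}

# Whole-brain parcellation: brain mask cut into nx x ny x nz blocks, labels
# assigned separately per hemisphere (x below/above midline -> L/R).
build_parcel_atlas <- function(brain_mask, n_blocks = c(4L, 4L, 2L)) {
  g <- dim(brain_mask)
  idx <- which(brain_mask != 0)
  coords <- arrayInd(idx, g)
  bx <- pmin(n_blocks[1] - 1L, ((coords[, 1] - 1L) * n_blocks[1]) %/% g[1])
  by <- pmin(n_blocks[2] - 1L, ((coords[, 2] - 1L) * n_blocks[2]) %/% g[2])
  bz <- pmin(n_blocks[3] - 1L, ((coords[, 3] - 1L) * n_blocks[3]) %/% g[3])
  lab <- 1L + bx + n_blocks[1] * (by + n_blocks[2] * bz)
  atlas <- array(0L, g)
  atlas[idx] <- lab
  labs <- sort(unique(lab))
  # bilateral naming: x-mirrored block pairs share a region name, L/R tag
  bx_of <- (labs - 1L) %% n_blocks[1]
  rest <- (labs - 1L) %/% n_blocks[1]
  hemi <- ifelse(bx_of < n_blocks[1] / 2, "L", "R")
  bxm <- pmin(bx_of, n_blocks[1] - 1L - bx_of)
  lookup <- data.frame(label = labs,
                       name = sprintf("parcel%02d", 1L + bxm + rest *
                                        (n_blocks[1] %/% 2L)),
                       hemisphere = hemi, division = "cortical",
                       stringsAsFactors = FALSE)
  list(atlas = atlas, lookup = lookup)
}

#' Simulate a synthetic cohort in memory
#'
#' Implements the generative model: voxel v at time t is
#' `sum_k M_k(v) c_k(t) g(v,k) + b_subject + noise`, with `M_k` the template
#' (whole brain) or the subregion loading pattern (inside the seed), `c_k`
#' smoothed, z-scored latent time-courses, and `g` a coupling factor carrying
#' the hemisphere offset, the between-participant gain and the fear-score
#' boost. Sessions of one subject share the subject effect but have
#' independent latents and noise.
#'
#' @param config a [synthetic_config()].
#' @return list of class `synthetic_cohort`: masks, atlases, lookups,
#'   templates, covariates, per subject-session `volume_series`, and a
#'   `truth` record (latents, template assignment, subregion rankings per
#'   network, fear slope).
#' @export
simulate_cohort <- function(config) {
  cfg <- validate_synthetic_config(config)
  g <- cfg$grid_shape
  tpts <- cfg$n_timepoints
  K <- cfg$n_networks
  spec <- cfg$seed_region_spec

  seed_atlas <- build_seed_atlas(spec, g)
  seed_mask <- (seed_atlas > 0) * 1L
  tset <- make_reference_templates(cfg$n_templates, g, cfg$rng_seed + 1L,
                                   avoid = seed_mask)
  parcel <- build_parcel_atlas(tset$brain_mask)
  seed_lookup <- spec[, c("label", "name", "hemisphere", "division")]

  with_seed(cfg$rng_seed, {
    assignment <- sample.int(cfg$n_templates, K)      # network k -> template
    scores <- make_fear_scores(
      cfg$n_subjects + cfg$n_subjects %% 2,
      cfg$fear_means, cfg$fear_sds,
      rng_seed = stats::runif(1, 1, 1e6))[seq_len(cfg$n_subjects)]
    med <- stats::median(scores)
    b_subj <- stats::rnorm(cfg$n_subjects, 0, cfg$subject_sd)
    age_band <- sample(c("22-25", "26-30", "31-35"), cfg$n_subjects,
                       replace = TRUE, prob = c(0.3, 0.45, 0.25))
    gender <- sample(c("F", "M"), cfg$n_subjects, replace = TRUE)

    # Per-voxel coupling, identical across subjects up to subject gain and
    # fear boost (both multiplicative): G0 is nvox x K.
    nvox <- prod(g)
    G0 <- matrix(0, nvox, K)
    for (k in seq_len(K)) G0[, k] <- as.numeric(tset$templates[[assignment[k]]])
    seed_idx <- which(seed_mask != 0)
    lab_of <- seed_atlas[seed_idx]
    name_of <- spec$name[match(lab_of, spec$label)]
    hemi_of <- spec$hemisphere[match(lab_of, spec$label)]
    seed_load <- cfg$loading_matrix[name_of, , drop = FALSE] *
      (1 + cfg$hemisphere_offset * (hemi_of == "R"))
    G0[seed_idx, ] <- seed_load

    fe <- cfg$fear_effect
    fear_vox <- if (!is.null(fe) && fe$slope != 0)
      seed_idx[name_of == fe$label] else integer(0)

    noise_sd <- 1 / cfg$network_snr
    subjects <- vector("list", cfg$n_subjects)
    latents <- list()
    for (i in seq_len(cfg$n_subjects)) {
      G <- G0 * (1 + b_subj[i])
      if (length(fear_vox) > 0)
        G[fear_vox, fe$network] <- G[fear_vox, fe$network] *
          (1 + fe$slope * (scores[i] - med))
      sessions <- vector("list", cfg$n_sessions_per_subject)
      for (s in seq_len(cfg$n_sessions_per_subject)) {
        C <- latent_timecourses(tpts, K)
        latents[[sprintf("sub-%02d_ses-%02d", i, s)]] <- C
        signal <- tcrossprod(C, G)                     # tpts x nvox
        noise <- ar1_noise(tpts, nvox, noise_sd, cfg$ar1_coef)
        dat <- t(signal + noise + b_subj[i])
        sessions[[s]] <- volume_series(array(dat, c(g, tpts)),
                                       tr = cfg$tr_seconds)
      }
      subjects[[i]] <- sessions
    }
  })

  rankings <- lapply(seq_len(K), function(k) {
    w <- cfg$loading_matrix[, k]
    names(sort(w[w > 0], decreasing = TRUE))
  })
  covariates <- data.frame(
    participant_id = sprintf("sub-%02d", seq_len(cfg$n_subjects)),
    age_band = age_band, gender = gender, fear_score = scores,
    stringsAsFactors = FALSE)

  structure(list(
    config = cfg, subjects = subjects,
    seed_mask = seed_mask, seed_atlas = seed_atlas, seed_lookup = seed_lookup,
    parcel_atlas = parcel$atlas, parcel_lookup = parcel$lookup,
    templates = tset$templates, brain_mask = tset$brain_mask,
    covariates = covariates,
    truth = list(latents = latents, template_assignment = assignment,
                 rankings = rankings,
                 fear_slope = if (is.null(cfg$fear_effect)) 0 else cfg$fear_effect$slope,
                 fear_label = if (is.null(cfg$fear_effect)) NA_character_ else cfg$fear_effect$label,
                 fear_network = if (is.null(cfg$fear_effect)) NA_integer_ else cfg$fear_effect$network,
                 subject_effects = b_subj, score_median = med)),
    class = "synthetic_cohort")
}

#' Write a synthetic cohort to disk
#'
#' Simulates (via [simulate_cohort()]) and writes a BIDS-like tree:
#' `sub-XX/ses-YY/func.nii.gz` 4D volumes, seed mask, subregion atlas,
#' whole-brain parcellation, template volumes, lookup TSVs, a participant
#' covariate TSV, the configuration as YAML, and the ground truth as JSON.
#'
#' @param config a [synthetic_config()].
#' @param out_dir output directory (created if needed).
#' @return the `synthetic_cohort`, invisibly, with attribute `paths`.
#' @export
make_cohort <- function(config, out_dir) {
  cohort <- simulate_cohort(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stopf("cannot create output directory '%s'", out_dir)
  cfg <- cohort$config
  for (i in seq_len(cfg$n_subjects)) {
    for (s in seq_len(cfg$n_sessions_per_subject)) {
      d <- file.path(out_dir, sprintf("sub-%02d", i), sprintf("ses-%02d", s))
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
      write_series(cohort$subjects[[i]][[s]], file.path(d, "func.nii.gz"))
    }
  }
  write_series(cohort$seed_mask, file.path(out_dir, "seed_mask.nii.gz"))
  write_series(cohort$seed_atlas, file.path(out_dir, "seed_atlas.nii.gz"))
  write_series(cohort$parcel_atlas, file.path(out_dir, "parcel_atlas.nii.gz"))
  write_series(cohort$brain_mask, file.path(out_dir, "brain_mask.nii.gz"))
  for (k in seq_along(cohort$templates))
    write_series(cohort$templates[[k]],
                 file.path(out_dir, sprintf("template-%02d.nii.gz", k)))
  utils::write.table(cohort$seed_lookup, file.path(out_dir, "seed_lookup.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$parcel_lookup, file.path(out_dir, "parcel_lookup.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$covariates, file.path(out_dir, "participants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg_out <- cfg
  cfg_out$seed_region_spec <- NULL
  cfg_out$loading_matrix <- apply(cfg$loading_matrix, 1, as.list, simplify = FALSE)
  yaml::write_yaml(cfg_out, file.path(out_dir, "config.yaml"))
  truth <- cohort$truth
  truth$latents <- lapply(truth$latents, function(m) round(unclass(m), 10))
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  attr(cohort, "paths") <- list(root = out_dir)
  invisible(cohort)
}
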