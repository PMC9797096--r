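# srica

Seed-restricted group ICA mapping of subregion co-activity networks.

High-resolution resting-state fMRI makes it possible to ask how the *internal*
structure of a small labeled brain region — the nuclei of the amygdala, say —
relates to large-scale co-activity networks. `srica` implements that analysis
as a tested, reusable pipeline for neuroimaging researchers:

1. **srICA** — group spatial ICA restricted to a seed mask: all
   subject-sessions are temporally concatenated, PCA-whitened to model order
   *d*, and unmixed with symmetric fixed-point ICA (log-cosh contrast), giving
   *d* spatial component maps over seed voxels.
2. **Dual regression** — stage 1 regresses each time point's seed pattern
   jointly on all component maps (per-session time-courses); stage 2 regresses
   every voxel on those time-courses (per-subject whole-brain Z maps,
   `Z = Φ⁻¹(F_t(t))`, clipped at ±38).
3. **Template matching and model-order selection** — group Z maps (one-sample
   t over subjects) are correlated with binary reference-network templates; a
   component *uniquely* detects a network when `r ≥ r* = 0.4` for that network
   only and no stronger candidate exists. The chosen *d* is the smallest one
   maximizing the number of uniquely detected networks.
4. **Mixed-model parcel statistics** — per-region mean Z values enter
   `Z ~ hemisphere + FC_map × brain_region + (1 | participant)` (REML,
   sum-to-zero coding, type-III F with Satterthwaite df, via
   lme4/lmerTest/emmeans). Effect contrasts (each map vs the mean of the
   others) describe the networks; summed pairwise z-ratios rank subregion
   contributions; a median-split covariate analysis tests group effects on
   subregion co-activity; a session split-half validates the maps.
5. **Synthetic cohorts** — a generator embeds known latent networks, seed
   clusters that cut across subregion labels, AR(1) noise, hemisphere and
   participant effects, and a covariate-dependent coupling boost, with full
   ground truth for parameter-recovery testing.

## Worked example

```r
library(srica)

cfg <- pipeline_config(
  d_min = 1, d_max = 10, rng_seed = 42,
  synthetic = synthetic_config(rng_seed = 42))   # 20 subjects x 2 sessions
res <- run_pipeline(cfg)

res$selection
#> <dimension_selection> chosen d = 3 (3 unique networks)
#>     d n_unique sum_matched_r
#> 1   1        1     0.6669472
#> 2   2        2     1.3135855
#> 3   3        3     2.3364976
#> 4   4        3     2.3372175
#> ...

res$assignment
#>   component  network network_index         r status
#> 1         1 network5             5 0.7721564 unique
#> 2         2 network1             1 0.7926161 unique
#> 3         3 network7             7 0.7717250 unique

res$rankings$IC2
#>   subregion summed_z_ratio rank
#> 1        Co       652.8537    1
#> 2       AAA       361.2461    2

res$fear$passing
#> [1] "Co"

round(res$validation$r, 3)
#>   IC1   IC2   IC3
#> 0.829 0.829 0.835
```

Reading the output: the sweep found that at model order 3 all three embedded
networks are uniquely detected (match correlations ≈ 0.77–0.79 against the
binary templates). The ranking table lists, for the component matched to
network 1, the subregions whose summed pairwise z-ratios are positive — here
Co then AAA, exactly the generating loading order. The covariate analysis
flags only the Co subregion (the one whose coupling the generator boosts with
the fear score), and the held-out-session maps correlate ≈ 0.83 with the
test-set maps with identical network assignment.

The same functions run on real data: `read_series()` /
`extract_masked_matrix()` / `highpass_filter()` / `regress_nuisance()` ingest
and preprocess NIfTI volumes, and `load_cohort()` reads a directory tree
written by `make_cohort()`. A thin command-line wrapper lives at
`inst/scripts/run-pipeline.R` (`--config config.yaml --out DIR --seed INT`).

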