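---
title: "Seed-restricted ICA mapping of subregion co-activity: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seed-restricted ICA mapping of subregion co-activity: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Small subcortical structures such as the amygdala are composed of nuclei far
smaller than the spatial scale at which resting-state functional connectivity
is usually analyzed. `srica` implements a pipeline for asking, with
high-resolution multi-subject rsfMRI: which signal clusters exist *inside* a
labeled seed region, which whole-brain co-activity network does each cluster
belong to, and how much does each labeled subregion (nucleus) contribute to
each network?

The stages are:

1. **Preprocessing** on top of already-cleaned data: a 2000 s temporal
   highpass filter and (optionally) regression of CSF/WM mean time-courses.
2. **Spatially-restricted group ICA (srICA)**: temporal concatenation of all
   subject-sessions restricted to the seed mask, PCA whitening to model
   order *d*, symmetric fixed-point ICA with the log-cosh contrast. The
   components are spatial maps over seed voxels.
3. **Dual regression**: stage 1 regresses each time point's seed pattern on
   all component maps jointly, giving per-session component time-courses;
   stage 2 regresses every brain voxel's time-course on those, giving
   per-subject whole-brain beta/t/Z maps. Z is the normal quantile of the
   Student-t tail probability, clipped at ±38.
4. **Template matching and model-order selection**: group Z maps (one-sample
   t over subjects, sessions averaged first) are correlated with binary
   reference-network templates over the brain mask. A component *uniquely*
   detects a network when its correlation with that network reaches r* = 0.4,
   all its other correlations stay below r*, and no other such candidate is
   more strongly correlated with that network. The selected model order is
   the smallest *d* maximizing the number of uniquely detected networks.
5. **Parcel statistics**: per-region mean Z values enter the mixed model
   `Z ~ hemisphere + FC_map * brain_region + (1 | participant)` (REML,
   sum-to-zero coding), with type-III F tests using Satterthwaite degrees of
   freedom. Post-hoc inference uses estimated marginal means: "effect"
   contrasts (one map against the mean of the others) for the whole-brain
   table, and all pairwise subregion contrasts within each map for the
   nucleus ranking — each subregion's row of pairwise z-ratios is summed,
   thresholded at > 0, and ranked.
6. **Covariate (fear) analysis**: participants are median-split on a fear
   score (ties to the low group); the model gains Gender, Age band and a
   Group × FC_map × brain_region interaction; when Group × brain_region is
   significant, low-vs-high contrasts per nucleus and per (nucleus, map) are
   Bonferroni-adjusted within their table. Age is dropped when
   nonsignificant.
7. **Validation**: whole-brain maps recomputed on held-out sessions from the
   *test-set* seed components are correlated component-wise with the test
   maps and re-matched to the templates.

## Mixed-model machinery

Model fitting uses `lme4`/`lmerTest` (REML, single random intercept,
Satterthwaite denominator df for the type-III tables) and `emmeans` for the
marginal-mean contrasts with asymptotic-normal z-ratios — the standard R
stack for exactly this class of models. Sum-to-zero factor coding is imposed
on every fixed factor so the type-III marginal tests are well defined. The
Bonferroni family is always the whole printed table.

Two conventions the literature leaves open are fixed here and tested:
pairwise z-ratios feeding the ranking are *signed* marginal-mean
differences (so the sums over all subregions cancel exactly — a conservation
property the test suite checks to 1e-10), and median-split ties go to the
low group.

## The synthetic cohort generator

Real high-resolution rsfMRI cohorts cannot ship with a package; the
generator produces cohorts with the statistical structure the analysis
assumes, plus the ground truth needed for parameter-recovery tests. The
generative model for voxel $v$ at time $t$ is

$$ y_v(t) = \sum_k M_k(v)\, g_{ik}(v)\, c_k(t) + b_i + \varepsilon_v(t), $$

with $M_k$ a binary whole-brain template (or the subregion loading pattern
inside the seed), $c_k$ latent network time-courses (moving-average-smoothed
Gaussian noise, z-scored — band-limited like resting-state fluctuations and
identifiably non-Gaussian in space), $\varepsilon$ AR(1) noise, and
$g_{ik}$ a coupling gain carrying a right-hemisphere offset, a
between-participant gain, and a fear-score boost.

Default reference conditions: 20 participants × 2 sessions, T = 200 at
TR = 1 s, K = 3 latent networks on a 24 × 24 × 12 grid with a 324-voxel,
18-label seed (9 subregions × 2 hemispheres), 7 disjoint reference
templates, per-voxel SNR 1, AR(1) coefficient 0.3, 10% between-participant
gain SD, +10% right-hemisphere coupling, and a 5% per-score-unit fear boost
of the Co subregion's coupling to network 1. Fear scores are a two-group
normal mixture (means 44.0/55.2, SDs 4.9/4.5), matching the published
group summaries the packaged t-test check reproduces.

Design choices worth recording:

* **Between-participant effect as a gain, not only an offset.** A purely
  additive DC offset would be annihilated by the highpass filter, leaving no
  between-participant variance for the random intercept to absorb. The
  subject effect therefore enters both as a DC offset (realistic in raw
  units) and as a multiplicative coupling gain `1 + b_i` that survives into
  the FC maps.
* **Sparse, disjoint seed clusters.** Each network loads two adjacent
  subregions with graded weights (1.0 and 0.6/0.7/0.5), three subregions
  stay unloaded. Clusters cutting across two labels mirror the finding the
  nucleus-ranking statistic is designed for, while disjoint supports keep
  the spatial sources independent — fully tiling the seed with equal-power
  sources makes the ICA rotation unidentifiable (symmetric spurious optima),
  which is a property of the *generator*, not of the estimator.
* **Template extent.** Templates occupy ~4% of the brain mask each (0.3 of
  each grid axis). Much smaller templates make the template correlation
  structurally tiny regardless of detection quality, because a binary
  regressor's correlation with a Z map scales with
  $\sqrt{p(1-p)}$ for coverage $p$; ~4% coverage reproduces the correlation
  regime (roughly 0.45–0.85) in which the matching rule and its r* = 0.4
  threshold are meant to operate.
* **Fear effect size.** The 5% per-score-unit boost, over the ±5.6-point
  group separation of the score mixture, modulates the designated
  subregion's coupling by roughly ±30% — an effect large enough to be
  detectable at n = 20 with Bonferroni correction, chosen a priori from the
  power arithmetic of the group contrast.

What the generator does *not* emulate: hemodynamics, head motion,
physiological noise, spatial autocorrelation of noise, family structure
between participants, and surface-based sampling. Passing recovery tests on
these cohorts therefore demonstrates correctness of the estimation
machinery under the model's own assumptions, not robustness to real-data
artifacts.

## Numerical choices

* Highpass: hard DFT threshold; every bin strictly below 1/cutoff Hz plus
  DC is zeroed, all others pass with unit gain. Deterministic and exactly
  oracle-checkable; with T = 900, TR = 1 s, cutoff 2000 s only the DC bin is
  affected, so the filter equals demeaning there. Nuisance regressors are
  filtered with the same filter before being regressed out, so the two
  steps commute.
* ICA: whitening retains exactly *d* principal components; symmetric
  fixed-point updates with tolerance 1e-6, at most 1000 iterations, up to 5
  restarts at seeds seed+1, … A model order can still fail (an oscillating
  rotation is genuine when the order is badly misspecified, e.g. d = 2 over
  three equal-power sources); the sweep records such orders as failed and
  selection skips them rather than aborting.
* Sign convention: every spatial map is flipped to nonnegative skewness, so
  cluster hotspots carry positive weight and downstream regression signs are
  stable. Maps are z-scored over seed voxels for comparability across model
  orders.
* Z statistics are computed through log-space tail probabilities and clipped
  at ±38 (the practical double-precision limit); zero-variance voxels in the
  group map go to 0 (zero mean) or ±38, counted in a warning.
* All internal linear algebra is float64 regardless of on-disk precision.

## Problem sizes used in the tests

The packaged tests run the full pipeline on the 20 × 2 reference cohorts
(dimension sweep 1..10 over five generator seeds; fear recovery and null
over five seeds each), 200 null replicates for the type-III calibration
check at 12 participants × 2 × 4 × 3 cells, and 1000 sign-flip permutations
for the permutation-uniformity check. These sizes give stable Monte-Carlo
verdicts for the calibration bands being tested while keeping the suite
runnable on a laptop.

## Known limitations

* The permutation test supports simple sign-flip exchangeability only; no
  TFCE, variance smoothing, or exchangeability blocks for family structure.
* Satterthwaite (not Kenward-Roger) df; a single random intercept only.
* The template-matching rule assumes binary templates; graded templates
  would need an overlap statistic (e.g. Dice) that is out of scope.
* The selection tie-break beyond "smallest d at maximal unique count" uses
  the summed matched correlation only as a reported diagnostic; it never
  overrides the smallest-d rule.
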