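Package: srica
Title: Seed-Restricted Group ICA Mapping of Subregion Co-Activity Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects signal clusters inside a labeled seed region of
    multi-subject resting-state fMRI data with spatially-restricted group
    independent component analysis (srICA), maps each cluster to a
    whole-brain co-activity network by dual regression, selects the ICA
    model order that best matches a set of reference network templates,
    ranks the contribution of each seed subregion (e.g. amygdala nucleus)
    to each network with mixed-model contrasts, and tests covariate
    effects on subregion co-activity. Includes a synthetic multi-subject
    4D data generator with known ground truth for parameter-recovery
    testing of the full pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    lme4,
    lmerTest,
    emmeans,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
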