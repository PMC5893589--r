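Package: boldvar
Title: Time-of-Day Analysis of BOLD Signal Variance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for time-of-day effects on
    resting-state and task fMRI BOLD signal variance. Generates synthetic
    multi-session studies with known ground truth; computes voxel-wise BOLD
    standard deviation, amplitude of low-frequency fluctuations (ALFF) and
    seed-based functional connectivity maps; performs group inference with
    repeated-measures ANOVA F-maps and permutation cluster-extent family-wise
    error correction; relates cluster-averaged variance to behavioral lapses
    via repeated-measures correlation and confound-adjusted linear mixed
    models; and estimates detection power for two-group connectivity
    differences by bootstrap resampling.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    signal,
    nlme,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
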