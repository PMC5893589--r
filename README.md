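# boldvar — time-of-day analysis of BOLD signal variance

Resting-state BOLD fluctuations vary over the day. `boldvar` implements a
complete, testable pipeline for studying that modulation: from 4-D fMRI
time series to voxel-wise variance maps, cluster-level group inference
across six scan times, brain-behavior association, confound-adjusted mixed
modeling, and a bootstrap power analysis — exercised end to end on a
synthetic study generator with known ground truth.

The scientific core, in the field's standard notation:

* **BOLD SD** per voxel: `SD = sqrt( Σᵢ (xᵢ − x̄)² / (n − 1) )` over the
  preprocessed time series; **ALFF** as mean spectral power in
  0.01–0.1 Hz; **seed connectivity** as Pearson r against the thalamic
  mean series.
* **Group inference**: voxel-wise one-way repeated-measures ANOVA over the
  six times of day (F = MS_ToD / MS_ToD×subject, df = (5, 65) at n = 14),
  cluster-forming threshold at p < 0.001 (F > 4.70), and cluster-extent
  FWE control at p < 0.05 by a **permutation maximum-cluster-size null**
  (time-of-day labels permuted within subject; sign-flips for one-sample
  contrast maps).
* **Post-hoc**: paired t-tests over all 15 ToD pairs, Bonferroni, with
  repeated-measures Cohen's d after Dunlap, `d = t·sqrt(2(1 − r)/n)`.
* **Brain–behavior**: the repeated-measures correlation (common
  within-subject slope ANCOVA), `r = sign(b)·sqrt(SSₓ/(SSₓ + SS_err))`,
  df = n_obs − n_subjects − 1.
* **Confound model**: REML linear mixed model with subject random
  intercept and AR(1) residual correlation over the 12 sessions, type III
  F-tests for ToD, day, physiology, motion and chronotype covariates, and
  ToD×covariate interactions.
* **Power**: bootstrap resampling of 14 epochs per group from wake / N1
  sleep analog pools, mass-univariate two-sample t with nested permutation
  cluster FWE, reporting the any-cluster detection rate.

The synthetic generator (`sim_config()`, `simulate_run()`,
`simulate_study()`) emulates the study design — 14 subjects × 6 times of
day (08:00…23:00) × 2 days, 210-volume rest runs at TR 2 s, task runs of
three 1-minute blocks with 11 stimuli each between four 25-s fixation
blocks — with a programmable twilight variance dip confined to sensory
regions, behaviorally coupled omission errors, and full ground-truth
serialization. See the methods vignette
(`vignettes/time-of-day-bold-variance.Rmd`) for the model and every
numerical choice.

## Worked example

```r
library(boldvar)

cfg <- sim_config(sd_profile = list(visual = c(0.8, 1, 1, 1, 0.8, 1)),
                  n_volumes_rest = 84, seed = 101)
sd_maps <- compute_study_maps(cfg, "rest", "sd", preprocess = TRUE)
fmap <- rm_anova_map(sd_maps$maps, sd_maps$mask)
thr <- critical_value("F", fmap$df, 0.001)     # 4.702
set.seed(1)
nulls <- perm_null_rm_anova(sd_maps$maps, sd_maps$mask, thr, n_perm = 500)
cluster_threshold(fmap, thr, nulls)
```

```
<cluster_table> 1 significant cluster(s); F > 4.702, 500 permutations
 cluster size p_fwe peak_x peak_y peak_z peak_stat
       1  200     0     11     22     11  51.40191
```

One significant cluster of 200 voxels — exactly the programmed "visual"
region (posterior box, peak at voxel (11, 22, 11)) — with corrected
p < 0.002: the 20% twilight variance dip is recovered and spatially
confined. Extracting the cluster mean per subject and time of day and
running the post-hoc tests shows 08:00 and 20:00 significantly below every
midday session (e.g. 11:00 − 08:00: t(13) = 9.97, Bonferroni p < 1e-5),
and the cluster-averaged SD ratio twilight/midday comes out at 0.817
against the programmed 0.8.

The `analysis/` directory holds the numbered drivers for the full
workflow — `01_simulate_study.R` through `06_power_bootstrap.R` — each a
short narrative script over the package functions that prints what it
found and writes tables under `results/`. Run them from the repository
root, e.g. `Rscript analysis/03_group_inference.R`.

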