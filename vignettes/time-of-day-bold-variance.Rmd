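---
title: "Time-of-day effects on BOLD signal variance: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-of-day effects on BOLD signal variance: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boldvar)
```

## The scientific question

Resting-state BOLD fluctuations are not constant over the day. The analysis
this package implements asks whether the *variance* of the spontaneous BOLD
signal — summarized voxel-wise as the time-series standard deviation (BOLD
SD) — is modulated by time of day; whether such modulation is confined to
sensory cortices and dips at twilight (the 08:00 and 20:00 sessions);
whether the dip persists during a visual detection task; whether lower
visual-cortex BOLD SD goes with fewer behavioral lapses (omission errors);
whether the effect survives adjustment for physiological, motion and
chronotype confounds; and whether a negative finding for thalamocortical
connectivity could be blamed on low statistical power at n = 14.

The design is 14 subjects scanned at six fixed clock times (08:00, 11:00,
14:00, 17:00, 20:00, 23:00) on two consecutive days; nine of them also
performed a close-to-threshold visual detection task in the scanner. Rest
runs are 210 volumes at TR = 2 s; task runs are three 1-minute task blocks
of 11 flashed stimuli alternating with four 25-s fixation blocks.

## The generative model of the synthetic study

Real data from the original study are not bundled. Instead, `sim_config()`
and `simulate_run()` define a fully specified generative model whose ground
truth is known, so every pipeline stage is testable end to end:

$$x_v(t) = \beta_i + g_i\, f_{r j}\,\bigl(a\, s_r(t) + \sigma\,
\varepsilon_v(t)\bigr) + d(t) + c\,\bigl(\mathrm{csf}(t) + \mathrm{wm}(t) +
\mathrm{mot}(t)\bigr)$$

for voxel $v$ in gray-matter region $r$, subject $i$, session (time of day)
$j$: a subject baseline $\beta_i \sim N(100, 10^2)$; a log-normal subject
amplitude $g_i$ (`subject_sd`, default 0.1 on the log scale); the
per-region, per-ToD multiplicative SD factor $f_{rj}$ (`sd_profile`); a
shared band-limited regional fluctuation $s_r$ of amplitude $a$
(`osc_amp`, default 1, unit-SD band-noise in 0.01–0.1 Hz, the band ALFF
integrates, so SD and ALFF respond coherently); spatially smoothed unit
white noise $\varepsilon_v$ scaled by `noise_sd` (default 0.5); scanner
drift $d$ (`drift_amp` 0.2, a random ramp plus a 0.003 Hz cosine — below
the high-pass cutoff, so preprocessing removes it); and leakage of the
CSF/WM/motion reference signals with weight `nuisance_coupling` (0.1).

Choices worth spelling out:

* **The twilight dip multiplies the whole stochastic part** (oscillation
  plus voxel noise), not just the oscillation, so the *empirical* SD ratio
  between twilight and midday recovers `twilight_dip` (default 0.8, a 20%
  dip) directly. Background voxels carry noise only and no ToD factor, so
  spatial confinement is checkable.
* **Connectivity ground truth**: the thalamus and a frontal "seed-target"
  cortical region share a common source with weight `fc_coupling`; all
  other regions have independent fluctuations. Task runs scale the
  oscillation amplitude by `task_amp_factor` (0.8), encoding the overall
  rest-to-task SD decrease.
* **Behavior**: omission errors per session are Poisson with (by default) a
  log-link rate tied to the subject's *current* visual-region SD factor,
  slope `behavior_coupling` = 4 and midday rate 2.2 — so twilight sessions
  ($f = 0.8$) have rate $2.2\,e^{-0.8} \approx 1$, matching the scale of
  lapse counts in this kind of task. A subject random effect
  (`subject_behavior_sd` 0.3) creates the between-subject variance that
  rmcorr must remove. The distributional family is a package choice; only
  means and SDs of lapse counts are ever compared. Reaction times carry no
  programmed ToD effect.
* **Spatial smoothness** comes from blurring the noise *field* (Gaussian,
  FWHM 1.5 voxels, renormalized to unit marginal variance) before region
  scaling, so cluster inference sees realistically sized clusters while
  per-voxel SD factors stay exact.
* **Missing covariates** reproduce the study pattern: chronotype missing
  for 2 subjects, wake-up time for 1, sleep debt for 3; the mixed model
  deletes listwise and reports the count.
* **Determinism**: every run's RNG seed is derived from the configuration
  seed and the run labels, so runs can be generated independently, in any
  order, with bitwise-identical results — full studies are streamed run by
  run rather than held in memory.

What the generator does *not* emulate: hemodynamic response shape, MR
physics, spatial misalignment or motion image artifacts (motion exists
only as regressor series plus optional signal leakage), non-Gaussian or
non-stationary noise, and anatomical geometry (regions are boxes inside an
ellipsoid). Passing tests therefore demonstrate that the *statistical
machinery* is correct and calibrated, not that real fMRI data meet its
assumptions.

## Temporal preprocessing

The pipeline order is fixed: discard the first 4 volumes (magnetic
saturation), high-pass filter, nuisance regression, masking; task runs
then drop fixation blocks, remove the first 5 volumes of each task block
and concatenate the rest. The filter is a 6th-order Butterworth high-pass
at 0.01 Hz applied forward and backward (zero phase), so variance maps are
not phase-shifted against the nuisance series and the effective
attenuation is the squared one-pass magnitude. The implementation uses
reflection padding of length 3 × order with steady-state initial
conditions — a constant series filters to zero at machine precision — and
is vectorized across voxels. The nuisance design has 16 regressors + an
intercept: 6 motion parameters, CSF and WM region means, and each series'
first backward difference (first element 0), all linearly detrended before
regression; rank-deficient designs drop collinear columns with a warning.
The CSF/WM reference series are means over the labeled compartments (the
original sphere coordinates are template-specific and meaningless on a
synthetic grid). An optional Gaussian smoothing utility exists but is off
for synthetic runs.

## Voxel-wise metrics

BOLD SD is the sample standard deviation ($n-1$ denominator). ALFF is the
**mean in-band power**: the two-sided spectrum is $P_j = |X_j|^2 / n$, so
the mean of $P_j$ over all $n$ bins equals the mean squared deviation
(Parseval) — note this is power, not the square-root amplitude convention
some tools use; band edges (0.01 and 0.1 Hz inclusive) are part of the
convention. Seed connectivity is the Pearson correlation of the
seed-region mean series with every in-mask voxel; zero-variance voxels get
r = 0 with a logged count rather than an error, so unattended null
simulations keep running. Day pairs are averaged voxel-wise per time of
day before any group statistics.

## Group inference

The ToD main effect is a voxel-wise one-way repeated-measures ANOVA
(6 levels, sphericity assumed; $F = MS_{ToD} / MS_{ToD \times subject}$,
df = (5, 65) at n = 14). Family-wise error is controlled by
**cluster-extent permutation testing** rather than random-field theory:
the cluster-forming threshold is the F (or t) value at p < 0.001
(`critical_value()` — 4.70 for F(5, 65), 3.31 for t(40)); time-of-day
labels are permuted within subject (sign-flips of per-subject contrast
maps for one-sample t-maps); each observed cluster's corrected p is the
proportion of permutations whose maximum suprathreshold cluster size
reaches the observed size. This substitution is deliberate: permutation
maximum-statistic nulls are exact under exchangeability, need no
smoothness estimation, and can be *validated by simulation* (the type-I
test below). Connectivity is the 18-neighborhood (SPM convention;
6/26 configurable); peak ties break to the lowest linear voxel index so
reports are deterministic; the default permutation count is 1000 with the
seed recorded (500 in the desk-scale harnesses), and fewer than 500
permutations for final inference is an error.

Cluster-size permutation p-values are discrete: under a weak-smoothness
null most permutation maxima are small integers, so the achievable
significance levels step coarsely and the test errs conservative — the
calibration check below asks only that the empirical rate falls inside
the 95% binomial band around the nominal 0.05.

Post-hoc tests are dependent two-tailed paired t-tests between all 15 ToD
pairs, Bonferroni-corrected, with repeated-measures Cohen's d after the
Dunlap correction, $d = t\sqrt{2(1-r)/n}$. The task analysis tests the
twilight contrast (mean of 08:00/20:00 minus mean of 11:00/14:00/17:00)
per voxel against zero inside the rest-defined visual cluster, with a
minimum-statistic conjunction across the six individual contrasts as the
consistency check; the rest-vs-task comparison is a paired t-test on
peak-voxel SD values averaged over ToD, Bonferroni over the number of
clusters. A small-volume variant restricts the permutation maximum
statistic to an a-priori sphere (the suprachiasmatic-region analog).

On real data the task one-sample t threshold was reported with df = 40;
a one-sample design over n = 9 subjects gives df = n − 1 = 8 from this
package's own design. `critical_value("t", 40, 0.001)` reproduces the
printed threshold, but the pipeline reports df from its own design — the
two are intentionally not reconciled.

## Behavior, rmcorr and the confound model

The behavioral ANOVA (`behavior_rm_anova`) uses `stats::aov` with a
Mauchly sphericity check and partial eta-squared
$\eta^2_p = F\,df_1 / (F\,df_1 + df_2)$. The brain-behavior association is
the **repeated-measures correlation**: an ANCOVA with subject as a
categorical factor and a common slope for x,
$r = \mathrm{sign}(b)\sqrt{SS_x / (SS_x + SS_{err})}$ with
df = n_obs − n_subjects − 1 — by construction invariant to adding any
per-subject constant, which is exactly what separates it from the pooled
Pearson correlation (the package's tests include a Simpson's-paradox
construction where the two disagree in sign). Day-averaged values enter
(9 subjects × 6 ToD = 54 pairs).

The confound model (`fit_confound_lmm`) is a REML linear mixed model:
ToD and day as repeated-measures fixed effects, heart rate, breathing
rate, body temperature, sleepiness, motion amplitude (mean per-parameter
max − min; the summary definition is a package choice), motion variance,
motion outlier count (time points beyond mean ± 2.5 SD of any parameter),
chronotype (MSFsc), sleep pressure (operationalized as wake-up time —
earlier waking = higher pressure at a fixed clock time) and sleep debt as
fixed covariates; a subject random intercept; and AR(1) residual
correlation across the 12 sessions in day-major order (the six ToD within
a day are the temporally adjacent measurements). Type III (marginal)
F-tests use sum-to-zero contrasts; denominator df follow nlme's
containment method — fractional SPSS-style Satterthwaite df are not
replicated, and the df method is recorded in every output. Numeric
covariates are mean-centered after listwise deletion: with
ToD×covariate interactions in the model, the marginal ToD test is then
evaluated at the covariate means rather than at covariate = 0, where it
would be meaningless. Non-convergent AR(1) fits fall back to compound
symmetry (then to independence) with a logged downgrade.

## Bootstrap power

`bootstrap_power()` draws `n_per_group` (14) epochs with replacement from
two labeled pools (93 wake / 54 N1-sleep analogs of ~3.5 min), computes
thalamic-seed connectivity maps per epoch, tests the group difference with
a mass-univariate pooled-variance two-sample two-tailed t (Welch optional)
at p < 0.001, cluster-corrects at FWE 0.05 with a nested group-label
permutation null (capped at 200, here 100, permutations per iteration; the
cap is recorded), and reports the voxel-wise proportion of significant
iterations plus the any-cluster power. Epoch connectivity maps are
computed once per pool and resampled — algebraically identical to
recomputing per draw. Because two *finite* pools from the same process
still differ by their own sampling noise — a real difference the bootstrap
faithfully detects — the null calibration resamples both groups from a
single pool. The original power check used an external sleep dataset; here
the qualitative conclusion (n = 14 suffices for a strong vigilance-scale
effect) is a calibration property: power ≥ 0.8 at a strong programmed
coupling difference, ≈ 0.05 under the null.

## Numerical and design choices

* Permutation p-values are plain proportions over the permutation set;
  with 500+ permutations the resolution (0.002) is far below the 0.05
  decision level.
* `rm_anova_map` sets F = 0 where the condition sum of squares is exactly
  zero (constant cells), rather than 0/0.
* The filter requires at least 3 × order samples; ALFF requires at least
  two frequency bins inside the band; cluster inference refuses fewer than
  500 permutations (configurable floor); empty masks, empty clusters,
  label mismatches and incomplete subject × ToD grids are errors, never
  silent repairs.
* Omission errors are drawn per session (integer counts); day-averaged
  values (possibly fractional) enter the ANOVA and rmcorr, matching the
  56-observation bookkeeping of the study design. Whether day-averaged or
  per-day values entered the original correlation is not stated; day
  averaging was chosen and is used consistently.
* Desk-scale problem sizes: the analysis scripts default to 84-volume rest
  runs (the full 210-volume protocol is a flag away and changes no
  conclusion at these effect sizes); the type-I calibration uses 200 null
  studies of 20-volume single-day runs at the full 24×24×18 grid with 500
  permutations each — run length and day count do not enter the
  permutation null's validity; the bootstrap power harness uses 200
  iterations with a nested cap of 100 permutations.

## Known limitations

The synthetic grid is 24×24×18 with box-shaped regions — cluster sizes and
peak coordinates are structurally, not anatomically, meaningful. The
generator's noise is Gaussian and stationary, so the calibration results
bound type-I behavior only under those assumptions. nlme's containment df
differ from SPSS MIXED's Satterthwaite-style fractional df, so printed
denominator df for the adjusted model are not comparable at the decimal
level. The permutation cluster test's discreteness makes it conservative
on weakly smoothed data, as quantified by the type-I calibration harness.
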