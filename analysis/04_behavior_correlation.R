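#!/usr/bin/env Rscript
# Behavior: time-of-day effect on omission errors and reaction times
# (repeated-measures ANOVA with Mauchly check and partial eta-squared,
# planned twilight-vs-midday paired tests), and the brain-behavior link:
# repeated-measures correlation between visual-region BOLD SD and omission
# errors at the same times of day.

suppressMessages(library(boldvar))
source("analysis/config.R")   # run from the repository root
dir.create("results", showWarnings = FALSE)

cfg <- study_config()
behav <- simulate_behavior(cfg)
bav <- aggregate(cbind(omission_errors, reaction_time) ~ subject + tod,
                 data = behav, FUN = mean)      # day-averaged

om <- behavior_rm_anova(bav, "omission_errors")
rt <- behavior_rm_anova(bav, "reaction_time")
cat(sprintf("Omission errors: F(%d, %d) = %.2f, p = %.4f, partial eta^2 = %.3f (Mauchly p = %.2f)\n",
            om$df1, om$df2, om$F, om$p, om$partial_eta_squared, om$mauchly_p))
cat(sprintf("Reaction times:  F(%d, %d) = %.2f, p = %.4f, partial eta^2 = %.3f\n",
            rt$df1, rt$df2, rt$F, rt$p, rt$partial_eta_squared))
cat("Reaction times carry no programmed time-of-day effect; omission errors do.\n\n")

pairs <- list(c("11:00", "08:00"), c("14:00", "08:00"), c("17:00", "08:00"),
              c("11:00", "20:00"), c("14:00", "20:00"), c("17:00", "20:00"))
planned <- planned_paired_tests(bav, pairs, "omission_errors")
write_tsv(planned, "results/behavior_planned_tests.tsv")
cat("Planned twilight-vs-midday comparisons (positive mean diff = more lapses at midday):\n")
print(planned, row.names = FALSE, digits = 3)

# brain-behavior: rmcorr of cluster-averaged SD with omission errors
vals <- read_tsv("results/visual_region_sd.tsv")
merged <- merge(vals, bav, by = c("subject", "tod"))
rc <- rmcorr(merged$value, merged$omission_errors, merged$subject)
cat("\nRepeated-measures correlation, visual-region BOLD SD vs omission errors:\n")
print(rc)
write_json_summary(unclass(rc), "results/rmcorr.json",
                   params = list(seed = cfg$seed, n_obs = rc$n_obs))
cat("Low twilight BOLD SD goes with fewer lapses; the common within-subject\n",
    "slope is positive, as programmed through the behavior coupling.\n")
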