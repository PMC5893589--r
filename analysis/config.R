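# Shared study configuration for the analysis scripts.
#
# 14 subjects, six scan times (08:00 ... 23:00) on two consecutive days,
# 24x24x18 grid. Rest runs are 84 volumes at TR 2 s here (the acquisition
# protocol's 210-volume runs make every step ~2.5x slower without changing
# any conclusion at these effect sizes; pass full = TRUE for the
# full-length protocol). A 20% SD dip at the twilight sessions is
# programmed into the visual region only, so that spatial confinement of
# the recovered effect is checkable against ground truth.

study_config <- function(full = FALSE, seed = 2024) {
  sim_config(
    sd_profile = list(visual = c(0.8, 1, 1, 1, 0.8, 1)),
    n_volumes_rest = if (full) 210 else 84,
    seed = seed)
}

PERM_SEED <- 77
N_PERM <- 500
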