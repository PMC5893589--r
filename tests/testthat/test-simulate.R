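test_that("configuration validation rejects degenerate designs", {
  expect_error(sim_config(grid_shape = c(2, 10, 10)), "degenerate grid")
  expect_error(sim_config(noise_sd = -1), "non-negative")
  expect_error(sim_config(tod_labels = c("14:00", "08:00")), "ordered")
  expect_error(sim_config(sd_profile = list(nowhere = rep(1, 6))), "region labels")
  expect_error(sim_config(sd_profile = list(visual = rep(-1, 6))), "positive")
  expect_error(sim_config(lowfreq_band = c(0.2, 0.3)), "Nyquist")
})

test_that("region map partitions the grid and masks behave", {
  reg <- default_region_map(c(24, 24, 18))
  expect_true(all(reg %in% seq_along(REGION_LEVELS)))
  # named regions all non-empty at the default grid
  for (r in REGION_LEVELS)
    expect_gt(sum(region_mask(reg, r)), 0)
  gm <- gray_matter_mask(reg)
  expect_false(any(gm & region_mask(reg, c("csf", "wm", "background"))))
  expect_error(region_mask(reg, "pineal"), "unknown region")
})

test_that("identical config and seed give byte-identical outputs", {
  cfg <- tiny_config(drift_amp = 0.2, nuisance_coupling = 0.1)
  a <- simulate_run(cfg, 2, 3, 1, "rest")
  b <- simulate_run(cfg, 2, 3, 1, "rest")
  expect_identical(a$run$data, b$run$data)
  expect_identical(a$nuisance, b$nuisance)
  expect_identical(simulate_behavior(cfg), simulate_behavior(cfg))
  expect_identical(simulate_covariates(cfg), simulate_covariates(cfg))
  cfg2 <- tiny_config(seed = 8, drift_amp = 0.2, nuisance_coupling = 0.1)
  expect_false(identical(simulate_run(cfg2, 2, 3, 1, "rest")$run$data, a$run$data))
})

test_that("a pure sinusoid of amplitude a has voxel SD a/sqrt(2)", {
  cfg <- tiny_config(osc_type = "sinusoid", osc_amp = 1.5, noise_sd = 0,
                     subject_sd = 0, sd_profile = list(),
                     n_volumes_rest = 200)
  g <- simulate_run(cfg, 1, 2, 1, "rest")
  sdm <- voxelwise_sd(g$run, region_mask(cfg$region_map, "visual"))
  vals <- sdm$values[region_mask(cfg$region_map, "visual")]
  expect_equal(mean(vals), 1.5 / sqrt(2), tolerance = 0.02)
})

test_that("doubling a region's SD factor doubles its signal SD exactly", {
  base <- tiny_config(sd_profile = list(visual = rep(1, 6)))
  dbl <- tiny_config(sd_profile = list(visual = rep(2, 6)))
  r1 <- simulate_run(base, 1, 1, 1, "rest")$run
  r2 <- simulate_run(dbl, 1, 1, 1, "rest")$run
  vis <- region_mask(base$region_map, "visual")
  s1 <- voxelwise_sd(r1, vis)$values[vis]
  s2 <- voxelwise_sd(r2, vis)$values[vis]
  expect_equal(s2, 2 * s1, tolerance = 1e-12)
})

test_that("time-of-day dip is confined to profiled regions", {
  dip <- c(0.8, 1, 1, 1, 0.8, 1)
  cfg <- tiny_config(n_subjects = 8, sd_profile = list(visual = dip),
                     smooth_fwhm = 1.5)
  reg <- cfg$region_map
  ratio_for <- function(region) {
    num <- den <- 0
    for (s in seq_len(cfg$n_subjects)) {
      sds <- sapply(seq_len(6), function(j) {
        run <- simulate_run(cfg, s, j, 1, "rest")$run
        mean(voxelwise_sd(run, region_mask(reg, region))$values, na.rm = TRUE)
      })
      num <- num + mean(sds[c(1, 5)])
      den <- den + mean(sds[c(2, 3, 4)])
    }
    num / den
  }
  expect_equal(ratio_for("visual"), 0.8, tolerance = 0.05)
  expect_equal(ratio_for("background"), 1, tolerance = 0.05)
  expect_equal(ratio_for("cortex"), 1, tolerance = 0.05)
})

test_that("omission-error rate follows the visual SD factor with the coupling sign", {
  cfg <- tiny_config(n_subjects = 10, n_task_subjects = 10, n_days = 2,
                     behavior_coupling = 4)
  b <- simulate_behavior(cfg)
  f <- cfg$sd_profile$visual[match(b$tod, cfg$tod_labels)]
  expect_gt(cor(f, b$omission_errors), 0)
  # null study: coupling removed, counts flat across tod
  bn <- simulate_behavior(null_config(cfg))
  fn <- tiny_config()$sd_profile$visual[match(bn$tod, cfg$tod_labels)]
  expect_lt(abs(cor(fn, bn$omission_errors)), 0.25)
  expect_true(all(bn$omission_errors >= 0))
  expect_true(all(bn$omission_errors == round(bn$omission_errors)))
})

test_that("null studies carry no twilight effect and record null truth", {
  cfg <- null_config(tiny_config(n_subjects = 6, smooth_fwhm = 1.5))
  expect_true(ground_truth(cfg, null = TRUE)$null)
  expect_length(cfg$sd_profile, 0)
  sm <- compute_study_maps(cfg, "rest", "sd", preprocess = FALSE)
  vis <- region_mask(cfg$region_map, "visual")
  vals <- extract_study_values(sm, vis)
  wide <- boldvar:::table_to_wide(vals)
  ratio <- mean(rowMeans(wide[, c(1, 5)]) / rowMeans(wide[, 2:4]))
  expect_equal(ratio, 1, tolerance = 0.05)
})

test_that("task runs follow the block design and carry fewer volumes of signal", {
  cfg <- tiny_config()
  lay <- task_block_layout(cfg$task_block_design, cfg$tr)
  expect_identical(lay$type, c("fixation", "task", "fixation", "task",
                               "fixation", "task", "fixation"))
  task_lens <- lay$last[lay$type == "task"] - lay$first[lay$type == "task"] + 1
  expect_equal(task_lens, rep(30, 3))
  g <- simulate_run(cfg, 1, 1, 1, "task")
  expect_identical(dim(g$run$data)[4], max(lay$last) + 4L)
})
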