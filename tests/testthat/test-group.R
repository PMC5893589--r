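test_that("critical values match the study design thresholds", {
  expect_equal(round(critical_value("F", c(5, 65), 0.001), 2), 4.70)
  expect_equal(round(critical_value("t", 40, 0.001), 2), 3.31)
  expect_equal(round(critical_value("t", 1e6, 0.025), 2), 1.96)
  expect_error(critical_value("t", 40, 0.7), "alpha")
  expect_error(critical_value("F", c(5, -1), 0.001), "degrees of freedom")
  expect_error(critical_value("t", c(5, 65), 0.001), "single df")
})

test_that("partial eta-squared follows its defining formula at reference values", {
  expect_equal(round(partial_eta_squared(2.67, 5, 40), 3), 0.250)
  expect_equal(round(partial_eta_squared(2.01, 5, 40), 3), 0.201)
  expect_identical(partial_eta_squared(0, 5, 40), 0)
  expect_error(partial_eta_squared(-1, 5, 40), "non-negative")
})

test_that("voxel-wise RM-ANOVA has the design df and matches the SS oracle", {
  mask <- array(TRUE, c(4, 3, 2))
  set.seed(31)
  cube <- array(rnorm(24 * 14 * 6), c(24, 14, 6))
  maps <- cube_to_maps(cube, mask)
  fmap <- rm_anova_map(maps, mask)
  expect_equal(fmap$df, c(5, 65))
  for (v in sample(24, 10))
    expect_equal(fmap$values[arrayInd(v, c(4, 3, 2))],
                 rm_anova_oracle(cube[v, , ]), tolerance = 1e-10)
})

test_that("RM-ANOVA F is invariant to per-subject constants and zero without condition variance", {
  mask <- array(TRUE, c(3, 2, 2))
  set.seed(32)
  cube <- array(rnorm(12 * 6 * 4), c(12, 6, 4))
  f1 <- rm_anova_map(cube_to_maps(cube, mask), mask)$values
  shifted <- cube + rep(rnorm(6) * 10, each = 12)  # per-subject offsets
  f2 <- rm_anova_map(cube_to_maps(shifted, mask), mask)$values
  expect_equal(f1, f2, tolerance = 1e-8)
  flat <- cube
  for (j in seq_len(4)) flat[, , j] <- flat[, , 1]  # equal within subject
  f3 <- rm_anova_map(cube_to_maps(flat, mask), mask)$values
  expect_true(all(f3 == 0))
})

test_that("incomplete subject-by-ToD designs are refused", {
  mask <- array(TRUE, c(2, 2, 1))
  cube <- array(rnorm(4 * 3 * 4), c(4, 3, 4))
  maps <- cube_to_maps(cube, mask)
  maps[[2]] <- maps[[2]][-1]
  expect_error(rm_anova_map(maps, mask), "incomplete design")
})

test_that("post-hoc paired tests Bonferroni-correct the printed comparison", {
  # construct a dataset whose 2nd-vs-1st comparison gives t(13) = 4.68 exactly
  n <- 14
  set.seed(33)
  e <- rnorm(n); e <- (e - mean(e)) / sd(e)          # mean 0, sd 1
  t_target <- 4.68
  diffs <- t_target / sqrt(n) + e
  base <- rnorm(n)
  tab <- rbind(
    data.frame(subject = 1:n, tod = "08:00", value = base),
    data.frame(subject = 1:n, tod = "11:00", value = base + diffs),
    data.frame(subject = 1:n, tod = "14:00", value = base + rnorm(n)))
  out <- posthoc_paired_tests(tab, m_comparisons = 15)
  row <- out[out$comparison == "11:00-08:00", ]
  expect_equal(row$t, 4.68, tolerance = 1e-10)
  expect_equal(row$df, 13)
  expect_equal(round(row$p_corrected, 3), 0.006)
  # identical conditions: t = 0, corrected p = 1
  tab2 <- rbind(data.frame(subject = 1:6, tod = "08:00", value = 1:6),
                data.frame(subject = 1:6, tod = "11:00", value = 1:6))
  out2 <- posthoc_paired_tests(tab2)
  expect_identical(out2$t, 0)
  expect_identical(out2$p_corrected, 1)
  expect_error(posthoc_paired_tests(tab2[c(1, 7), ]), "at least 3")
})

test_that("paired t matches the textbook oracle on random pairs", {
  for (i in 1:100) {
    set.seed(i)
    x <- rnorm(10); y <- rnorm(10)
    row <- boldvar:::paired_row(x, y, "x-y")
    d <- x - y
    expect_equal(row$t, mean(d) / (sd(d) / sqrt(10)), tolerance = 1e-12)
    expect_equal(row$p, 2 * pt(-abs(row$t), 9), tolerance = 1e-12)
  }
})

test_that("repeated-measures Cohen's d follows the Dunlap formula", {
  expect_equal(cohens_d_rm(3, 0.5, 16), 3 / sqrt(16))
  expect_identical(cohens_d_rm(0, 0.3, 10), 0)
  expect_error(cohens_d_rm(2, 1, 10), "undefined")
  # summary-statistic oracle: with equal condition SDs, d = (M1 - M2) / SD
  set.seed(34)
  n <- 8
  x <- rnorm(n); x <- (x - mean(x)) / sd(x)
  z <- rnorm(n); z <- residuals(lm(z ~ x)); z <- z / sd(z)
  r_target <- 0.6
  y <- r_target * x + sqrt(1 - r_target^2) * z       # sd 1, cor r_target
  x2 <- 2 + x; y2 <- 1.3 + y                          # equal SDs, known means
  tt <- t.test(x2, y2, paired = TRUE)
  d <- cohens_d_rm(unname(tt$statistic), cor(x2, y2), n)
  expect_equal(d, (mean(x2) - mean(y2)) / 1, tolerance = 1e-10)
})

test_that("twilight contrast t-map matches a one-sample oracle and zero cases", {
  mask <- array(TRUE, c(3, 3, 2))
  set.seed(35)
  cube <- array(rnorm(18 * 9 * 6), c(18, 9, 6))
  maps <- cube_to_maps(cube, mask, tods = c("08:00", "11:00", "14:00",
                                            "17:00", "20:00", "23:00"))
  tmap <- twilight_contrast_map(maps, mask)
  expect_equal(tmap$df, 8)
  con <- (cube[, , 1] + cube[, , 5]) / 2 - (cube[, , 2] + cube[, , 3] + cube[, , 4]) / 3
  for (v in sample(18, 6)) {
    tt <- t.test(con[v, ])
    expect_equal(tmap$values[arrayInd(v, c(3, 3, 2))], unname(tt$statistic),
                 tolerance = 1e-12)
  }
  flat <- cube; for (j in 2:6) flat[, , j] <- flat[, , 1]
  t0 <- twilight_contrast_map(cube_to_maps(flat, mask,
                                           tods = c("08:00", "11:00", "14:00",
                                                    "17:00", "20:00", "23:00")), mask)
  expect_true(all(t0$values == 0))
})

test_that("conjunction is the voxel-wise minimum and is monotone", {
  set.seed(36)
  maps <- lapply(1:3, function(i) stat_map(array(rnorm(24), c(4, 3, 2)), "t", df = 8))
  conj <- conjunction_map(maps)
  expect_equal(conj$values, pmin(maps[[1]]$values,
                                 pmin(maps[[2]]$values, maps[[3]]$values)))
  expect_equal(conjunction_map(list(maps[[1]], maps[[1]]))$values, maps[[1]]$values)
  zero <- stat_map(array(0, c(4, 3, 2)), "t", df = 8)
  expect_true(all(conjunction_map(list(maps[[1]], zero))$values <= 0))
  # monotone: adding a contrast never increases the statistic
  expect_true(all(conjunction_map(c(maps, list(zero)))$values <= conj$values))
  bad <- stat_map(array(0, c(4, 3, 3)), "t", df = 8)
  expect_error(conjunction_map(list(maps[[1]], bad)), "shape")
  expect_error(conjunction_map(maps[1]), "at least 2")
})

test_that("small-volume test reduces to the ROI maximum with a valid permutation p", {
  mask <- array(TRUE, c(5, 4, 3))
  set.seed(37)
  cube <- array(rnorm(60 * 8 * 4), c(60, 8, 4))
  maps <- cube_to_maps(cube, mask)
  roi <- array(FALSE, c(5, 4, 3)); roi[2:3, 2:3, 2] <- TRUE
  set.seed(1)
  res <- small_volume_test(maps, mask, roi, n_perm = 200)
  fmap <- rm_anova_map(maps, mask)
  expect_equal(res$max_stat, max(fmap$values[roi]), tolerance = 1e-12)
  expect_gte(res$p_corrected, 0)
  expect_lte(res$p_corrected, 1)
  # sphere interface and empty intersection error
  res2 <- small_volume_test(maps, mask, list(center = c(3, 2, 2), radius = 1.5),
                            n_perm = 200)
  expect_true(res2$n_roi_voxels > 1)
  outside <- array(FALSE, c(5, 4, 3))
  expect_error(small_volume_test(maps, mask, outside), "empty|intersect")
  # single-voxel ROI: corrected p equals that voxel's permutation p
  one <- array(FALSE, c(5, 4, 3)); one[2, 2, 2] <- TRUE
  set.seed(9)
  res1 <- small_volume_test(maps, mask, one, n_perm = 150)
  mc <- boldvar:::map_cube(maps, mask)
  vidx <- which(as.vector(one)[mc$mask_idx])
  set.seed(9)
  null_v <- unlist(boldvar:::rm_anova_permute(mc$cube, 150,
                                              function(Fv) Fv[vidx]))
  expect_equal(res1$p_corrected, mean(null_v >= res1$max_stat))
})

test_that("rest-versus-task comparison detects programmed amplitude reduction", {
  # identical values: no difference
  same <- rest_vs_task_sd(rep(1:5, 2), rep(1:5, 2))
  expect_identical(same$t, 0)
  expect_identical(same$mean_diff, 0)
  expect_error(rest_vs_task_sd(1:4, 1:5), "paired")
  # paired-t oracle
  set.seed(38)
  r <- rnorm(9, 10); tk <- rnorm(9, 9)
  row <- rest_vs_task_sd(r, tk, m_comparisons = 2)
  tt <- t.test(r, tk, paired = TRUE)
  expect_equal(row$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(row$p_corrected, min(1, 2 * tt$p.value))
  # synthetic study: task oscillation amplitude reduced by task_amp_factor
  cfg <- tiny_config(n_subjects = 6, n_task_subjects = 6, task_amp_factor = 0.7,
                     seed = 99)
  vis <- region_mask(cfg$region_map, "visual")
  rest_sd <- sapply(1:6, function(s) {
    mean(sapply(1:6, function(j)
      mean(voxelwise_sd(simulate_run(cfg, s, j, 1, "rest")$run, vis)$values, na.rm = TRUE)))
  })
  task_sd <- sapply(1:6, function(s) {
    mean(sapply(1:6, function(j) {
      run <- simulate_run(cfg, s, j, 1, "task")$run
      run <- concat_task_blocks(discard_leading_volumes(run, 4),
                                cfg$task_block_design)
      mean(voxelwise_sd(run, vis)$values, na.rm = TRUE)
    }))
  })
  res <- rest_vs_task_sd(rest_sd, task_sd)
  expect_gt(res$mean_diff, 0)
  expect_lt(res$p, 0.05)
})
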