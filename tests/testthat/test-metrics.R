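test_that("voxel-wise SD evaluates the sample formula", {
  run <- bold_run(array(rep(c(1, 2, 3, 4, 5), each = 4), c(2, 2, 1, 5)), tr = 2)
  expect_equal(unique(as.vector(voxelwise_sd(run)$values)), sqrt(2.5))
  cst <- bold_run(array(3, c(2, 2, 1, 10)), tr = 2)
  expect_true(all(voxelwise_sd(cst)$values == 0))
  # 2 volumes is the minimum; fewer cannot even be constructed
  expect_silent(voxelwise_sd(bold_run(array(1:8, c(2, 2, 1, 2)), tr = 2)))
  expect_error(bold_run(array(1:4, c(2, 2, 1, 1)), tr = 2), "at least 2")
})

test_that("SD is homogeneous of degree one and matches apply(sd) on random runs", {
  for (i in 1:100) {
    set.seed(i)
    run <- rand_run(c(3, 3, 2), t_len = sample(5:40, 1), seed = i)
    m <- voxelwise_sd(run)
    oracle <- apply(run$data, 1:3, sd)
    expect_equal(m$values, oracle, tolerance = 1e-12)
    c_run <- run; c_run$data <- run$data * -2.5
    expect_equal(voxelwise_sd(c_run)$values, 2.5 * oracle, tolerance = 1e-12)
  }
})

test_that("ALFF isolates in-band power and satisfies Parseval", {
  t_len <- 210; tr <- 2
  tt <- seq_len(t_len) - 1
  s <- sin(2 * pi * 0.05 * tt * tr)
  run <- bold_run(array(rep(s, each = 4), c(2, 2, 1, t_len)), tr = tr)
  alff <- voxelwise_alff(run)$values[1, 1, 1]
  # out-of-band mean power via the same spectrum
  ps <- power_spectrum(s - mean(s), tr)
  half <- ps[ps$freq <= 1 / (2 * tr), ]
  in_band <- half$freq >= 0.01 & half$freq <= 0.1
  expect_equal(alff, mean(half$power[in_band]), tolerance = 1e-10)
  expect_gt(alff / mean(half$power[!in_band & half$freq > 0]), 100)
  # constant series has zero power anywhere
  cst <- bold_run(array(5, c(2, 2, 1, 60)), tr = 2)
  expect_true(all(voxelwise_alff(cst)$values == 0))
  # Parseval: mean power over ALL bins = mean squared deviation
  for (i in 1:100) {
    set.seed(i)
    x <- rnorm(sample(20:120, 1))
    ps <- power_spectrum(x - mean(x), tr = 2)
    expect_equal(mean(ps$power), mean((x - mean(x))^2), tolerance = 1e-10)
  }
})

test_that("ALFF rejects bands without at least two bins", {
  run <- rand_run(c(2, 2, 1), t_len = 20)
  expect_error(voxelwise_alff(run, band = c(0.09, 0.1)), "fewer than 2")
})

test_that("seed connectivity reproduces textbook correlations", {
  shape <- c(5, 2, 2); t_len <- 40
  set.seed(11)
  dat <- array(rnorm(prod(shape) * t_len), c(shape, t_len))
  seed <- array(FALSE, shape); seed[1, 1, 1] <- TRUE
  s <- dat[1, 1, 1, ]
  dat[2, 1, 1, ] <- s                 # identical
  dat[3, 1, 1, ] <- -s                # negated
  run <- bold_run(dat, tr = 2)
  fc <- seed_fc_map(run, seed)
  expect_equal(fc$values[1, 1, 1], 1)
  expect_equal(fc$values[2, 1, 1], 1)
  expect_equal(fc$values[3, 1, 1], -1)
  # 20-voxel toy vs stats::cor oracle
  for (v in seq_len(prod(shape))) {
    co <- arrayInd(v, shape)
    expect_equal(fc$values[co[1], co[2], co[3]],
                 cor(dat[co[1], co[2], co[3], ], s), tolerance = 1e-12)
  }
})

test_that("zero-variance voxels yield r = 0 with a warning", {
  shape <- c(3, 2, 1); t_len <- 30
  set.seed(12)
  dat <- array(rnorm(prod(shape) * t_len), c(shape, t_len))
  dat[2, 1, 1, ] <- 4
  seed <- array(FALSE, shape); seed[1, 1, 1] <- TRUE
  expect_warning(fc <- seed_fc_map(bold_run(dat, tr = 2), seed), "zero-variance")
  expect_equal(fc$values[2, 1, 1], 0)
})

test_that("day averaging is an exact voxel-wise mean with label checks", {
  set.seed(13)
  a <- stat_map(array(rnorm(24), c(4, 3, 2)), "SD", tod = "08:00", day = 1)
  b <- stat_map(array(rnorm(24), c(4, 3, 2)), "SD", tod = "08:00", day = 2)
  expect_equal(average_days(a, b)$values, (a$values + b$values) / 2)
  expect_equal(average_days(a, a)$values, a$values)
  z <- a; z$values[] <- 0
  expect_equal(average_days(z, b)$values, b$values / 2)
  b2 <- b; b2$tod <- "11:00"
  expect_error(average_days(a, b2), "pairing")
  b3 <- stat_map(array(0, c(4, 3, 2)), "ALFF", tod = "08:00")
  expect_error(average_days(a, b3), "different types")
})

test_that("cluster extraction equals the masked mean and the peak value", {
  set.seed(14)
  m <- stat_map(array(rnorm(60), c(5, 4, 3)), "SD")
  cl <- array(runif(60) < 0.3, c(5, 4, 3)); cl[1, 1, 1] <- TRUE
  expect_equal(extract_cluster_mean(m, cl), mean(m$values[cl]))
  single <- array(FALSE, c(5, 4, 3)); single[2, 3, 1] <- TRUE
  expect_equal(extract_cluster_mean(m, single), m$values[2, 3, 1])
  unif <- m; unif$values[] <- 4.2
  expect_equal(extract_cluster_mean(unif, cl), 4.2)
  expect_equal(extract_cluster_mean(m, cl, at = "peak", peak_voxel = c(2, 3, 1)),
               m$values[2, 3, 1])
  expect_error(extract_cluster_mean(m, array(FALSE, c(5, 4, 3))), "empty")
})

test_that("in-band amplitude moves SD and ALFF together", {
  cfg <- tiny_config(osc_amp = 0.5, seed = 21)
  cfg2 <- tiny_config(osc_amp = 2, seed = 21)
  vis <- region_mask(cfg$region_map, "visual")
  r1 <- simulate_run(cfg, 1, 1, 1, "rest")$run
  r2 <- simulate_run(cfg2, 1, 1, 1, "rest")$run
  expect_gt(mean(voxelwise_sd(r2, vis)$values[vis]),
            mean(voxelwise_sd(r1, vis)$values[vis]))
  expect_gt(mean(voxelwise_alff(r2, vis)$values[vis]),
            mean(voxelwise_alff(r1, vis)$values[vis]))
})
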