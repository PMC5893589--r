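test_that("leading-volume discard trims runs and nuisance in lockstep", {
  run <- rand_run(c(4, 4, 3), t_len = 210)
  expect_identical(dim(discard_leading_volumes(run, 4)$data)[4], 206L)
  expect_identical(discard_leading_volumes(run, 0), run)
  expect_error(discard_leading_volumes(run, 210), "empty")
  nu <- rand_nuisance(210)
  expect_identical(nrow(trim_nuisance(nu, 4)), 206L)
  expect_error(trim_nuisance(nu, 210), "empty")
})

test_that("high-pass filter removes DC exactly and passes the band", {
  const <- rep(7, 300)
  out <- highpass_filter(const, tr = 2)
  expect_lt(max(abs(out)), 1e-8 * 7)
  # 0.05 Hz = 5x cutoff: amplitude preserved within 2% (RMS measure, since
  # 10 samples/period never sample the crest)
  t <- 0:599
  s <- sin(2 * pi * 0.05 * t * 2)
  f <- highpass_filter(s, tr = 2)
  expect_equal(sqrt(2 * mean(f[100:500]^2)), 1, tolerance = 0.02)
  # 0.002 Hz = 0.2x cutoff: 6th-order zero-phase attenuation is far below 1%
  s2 <- sin(2 * pi * 0.002 * t * 2)
  f2 <- highpass_filter(s2, tr = 2)
  expect_lt(sqrt(2 * mean(f2^2)), 0.01)
})

test_that("filtering is linear and preserves length and shape", {
  set.seed(3)
  u <- rnorm(150); v <- rnorm(150)
  lhs <- highpass_filter(2.5 * u - 1.3 * v, tr = 2)
  rhs <- 2.5 * highpass_filter(u, tr = 2) - 1.3 * highpass_filter(v, tr = 2)
  expect_equal(lhs, rhs, tolerance = 1e-9)
  expect_length(lhs, 150)
  run <- rand_run(c(4, 3, 3), t_len = 60)
  expect_identical(dim(highpass_filter(run)$data), dim(run$data))
  expect_error(highpass_filter(u, tr = 2, cutoff_hz = 0.3), "Nyquist")
})

test_that("nuisance regression annihilates the design space", {
  t_len <- 80
  nu <- rand_nuisance(t_len, seed = 5)
  X <- boldvar:::nuisance_design(as.matrix(nu))
  set.seed(6)
  beta <- rnorm(ncol(X))
  combo <- as.numeric(X %*% beta)
  run <- bold_run(array(rep(combo, each = 8), c(2, 2, 2, t_len)), tr = 2)
  res <- regress_nuisance(run, nu)
  expect_lt(max(abs(res$data)), 1e-8 * max(abs(combo)))
})

test_that("residuals are orthogonal to every regressor and match a naive solve", {
  t_len <- 50
  nu <- rand_nuisance(t_len, seed = 8)
  set.seed(9)
  y <- rnorm(t_len)
  run <- bold_run(array(y, c(1, 1, 1, t_len)), tr = 2)
  res <- as.numeric(regress_nuisance(run, nu)$data)
  X <- boldvar:::nuisance_design(as.matrix(nu))
  for (j in seq_len(ncol(X)))
    expect_lt(abs(sum(res * X[, j])), 1e-6 * sqrt(sum(res^2) * sum(X[, j]^2)))
  # brute-force normal equations oracle
  beta <- solve(crossprod(X), crossprod(X, y))
  expect_equal(res, as.numeric(y - X %*% beta), tolerance = 1e-10)
})

test_that("collinear nuisance columns are dropped with a warning", {
  t_len <- 60
  nu <- rand_nuisance(t_len, seed = 10)
  nu$wm <- nu$csf          # exact collinearity
  run <- rand_run(c(2, 2, 2), t_len = t_len)
  expect_warning(regress_nuisance(run, nu), "rank-deficient")
})

test_that("task-block concatenation trims and joins the printed design", {
  design <- list(task_s = 60, fixation_s = 25, n_task_blocks = 3,
                 n_fixation_blocks = 4, n_stimuli_per_block = 11,
                 n_lead_volumes = 4)
  lay <- task_block_layout(design, tr = 2)
  run <- rand_run(c(3, 3, 2), t_len = max(lay$last), condition = "task")
  expect_identical(dim(concat_task_blocks(run, design, 5)$data)[4], 75L)
  expect_identical(dim(concat_task_blocks(run, design, 0)$data)[4], 90L)
  expect_error(concat_task_blocks(run, design, 30), "fewer volumes")
  short <- rand_run(c(3, 3, 2), t_len = 50, condition = "task")
  expect_error(concat_task_blocks(short, design), "exceeds run length")
})

test_that("concatenated volumes preserve temporal order of task blocks", {
  design <- list(task_s = 60, fixation_s = 25, n_task_blocks = 3,
                 n_fixation_blocks = 4, n_stimuli_per_block = 11,
                 n_lead_volumes = 4)
  lay <- task_block_layout(design, tr = 2)
  t_len <- max(lay$last)
  ramp <- array(rep(seq_len(t_len), each = 4), c(2, 2, 1, t_len))
  run <- bold_run(ramp, tr = 2, condition = "task")
  out <- concat_task_blocks(run, design, 5)
  kept <- out$data[1, 1, 1, ]
  expect_false(is.unsorted(kept))
  expect_identical(length(kept), 75L)
  # kept indices exclude every fixation volume and each block's first 5
  fix_idx <- unlist(Map(seq, lay$first[lay$type == "fixation"],
                        lay$last[lay$type == "fixation"]))
  expect_true(!any(kept %in% fix_idx))
})

test_that("optional spatial smoothing preserves constants and matches brute force", {
  cst <- array(3.7, c(6, 5, 4))
  expect_equal(gaussian_smooth(cst, 2), cst, tolerance = 1e-12)
  set.seed(77)
  a <- array(rnorm(6 * 5 * 4), c(6, 5, 4))
  sm <- gaussian_smooth(a, 1.5)
  # brute-force separable convolution with edge-renormalized kernels
  sigma <- 1.5 / (2 * sqrt(2 * log(2)))
  w <- function(n) {
    K <- exp(-outer(1:n, 1:n, "-")^2 / (2 * sigma^2))
    K[abs(outer(1:n, 1:n, "-")) > ceiling(3 * sigma)] <- 0
    K / rowSums(K)
  }
  K1 <- w(6); K2 <- w(5); K3 <- w(4)
  ref <- array(0, c(6, 5, 4))
  for (x in 1:6) for (y in 1:5) for (z in 1:4)
    ref[x, y, z] <- sum(outer(outer(K1[x, ], K2[y, ]), K3[z, ]) * a)
  expect_equal(sm, ref, tolerance = 1e-10)
  run <- rand_run(c(6, 5, 4), t_len = 3)
  expect_identical(dim(gaussian_smooth(run, 1.5)$data), dim(run$data))
  expect_identical(gaussian_smooth(run, 0), run)
})
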