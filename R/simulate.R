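# Synthetic study generator.
#
# Signal model, per voxel v in gray region r, subject i, time of day j:
#   x_v(t) = base_i + g_i * f_rj * (a * s_r(t) + sigma * eps_v(t))
#            + drift(t) + c_nuis * (csf(t) + wm(t) + motion(t))
# where s_r is a shared band-limited regional fluctuation (thalamus and
# the cortical seed-target share a common source with weight fc_coupling),
# eps is spatially smoothed unit white noise, f_rj the per-region
# time-of-day SD factor, and g_i a log-normal subject scaling. Background
# voxels carry noise only; CSF/WM voxels carry their own reference signal.

# deterministic per-run seed so runs can be generated in any order
run_seed <- function(config, subject, tod_idx, day, condition, stream = 0L) {
  cond <- if (condition == "task") 1L else 0L
  idx <- (((subject - 1L) * 8L + (tod_idx - 1L)) * 4L + (day - 1L)) * 2L + cond
  as.integer((as.double(config$seed) * 2654435 + idx * 1009 + stream * 97 + 12345) %% 2147483647)
}

# band-limited unit-SD Gaussian series via FFT masking
band_noise <- function(t_len, tr, band) {
  x <- stats::rnorm(t_len)
  X <- stats::fft(x)
  f <- (seq_len(t_len) - 1) / (t_len * tr)
  f <- pmin(f, 1 / tr - f)  # two-sided frequency axis
  keep <- f >= band[1] & f <= band[2]
  X[!keep] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / t_len
  s <- stats::sd(y)
  if (s == 0) stop("lowfreq_band contains no frequency bin at this run length")
  y / s
}

# separable Gaussian blur matrices with edge renormalization
blur_kernel <- function(n, sigma) {
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  K <- exp(-d^2 / (2 * sigma^2))
  K[d > ceiling(3 * sigma)] <- 0
  K / rowSums(K)
}

# smooth iid noise (voxels x time, on the full grid) and renormalize to
# unit marginal variance so `noise_sd` keeps its meaning. Reshapes use
# `dim<-` (no copy); only the three matrix products and transposes allocate.
smooth_noise_field <- function(eps, grid_shape, fwhm) {
  if (fwhm <= 0) return(eps)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]
  t_len <- ncol(eps)
  K1 <- blur_kernel(nx, sigma); K2 <- blur_kernel(ny, sigma); K3 <- blur_kernel(nz, sigma)
  a <- eps
  dim(a) <- c(nx, ny * nz * t_len)
  a <- K1 %*% a
  dim(a) <- c(nx, ny, nz, t_len)
  a <- aperm(a, c(2, 1, 3, 4))
  dim(a) <- c(ny, nx * nz * t_len)
  a <- K2 %*% a
  dim(a) <- c(ny, nx, nz, t_len)
  a <- aperm(a, c(3, 2, 1, 4))
  dim(a) <- c(nz, nx * ny * t_len)
  a <- K3 %*% a
  dim(a) <- c(nz, nx, ny, t_len)
  a <- aperm(a, c(2, 3, 1, 4))
  dim(a) <- c(nx * ny * nz, t_len)
  sd_map <- sqrt(outer(outer(rowSums(K1^2), rowSums(K2^2)), rowSums(K3^2)))
  a / as.vector(sd_map)
}

# subject-level random effects, drawn once per study, order-independent
study_subject_effects <- function(config) {
  set.seed(as.integer((as.double(config$seed) * 48271 + 7) %% 2147483647))
  n <- config$n_subjects
  list(
    baseline   = stats::rnorm(n, 100, 10),
    scale      = exp(stats::rnorm(n, 0, config$subject_sd)),
    behavior_u = stats::rnorm(n, 0, config$subject_behavior_sd)
  )
}

# SD factor for region `r` at tod index j (1 when region not in the profile)
sd_factor <- function(config, region, tod_idx) {
  p <- config$sd_profile[[region]]
  if (is.null(p)) 1 else p[tod_idx]
}

#' Volume indices of task and fixation blocks
#'
#' Assigns each volume (after the leading saturation volumes) to the block
#' active at its onset. Blocks alternate fixation/task/fixation/... starting
#' and ending with fixation.
#'
#' @param design task block design list (see [sim_config()]).
#' @param tr repetition time, seconds.
#' @return data.frame with columns block, type ("fixation"/"task"),
#'   first, last (1-based volume indices relative to the first post-lead
#'   volume).
#' @export
task_block_layout <- function(design, tr) {
  types <- character(0); durs <- numeric(0)
  for (b in seq_len(design$n_task_blocks)) {
    types <- c(types, "fixation", "task")
    durs <- c(durs, design$fixation_s, design$task_s)
  }
  types <- c(types, "fixation"); durs <- c(durs, design$fixation_s)
  if (length(types) != design$n_task_blocks + design$n_fixation_blocks)
    stop("block design inconsistent: expected ", design$n_fixation_blocks,
         " fixation blocks interleaving ", design$n_task_blocks, " task blocks")
  ends <- cumsum(durs)
  starts <- c(0, ends[-length(ends)])
  n_vol <- floor(sum(durs) / tr)
  onset <- (seq_len(n_vol) - 1) * tr
  blk <- findInterval(onset, starts)
  data.frame(block = seq_along(types), type = types,
             first = vapply(seq_along(types), function(b) min(which(blk == b)), 1L),
             last = vapply(seq_along(types), function(b) max(which(blk == b)), 1L))
}

task_run_volumes <- function(config) {
  lay <- task_block_layout(config$task_block_design, config$tr)
  max(lay$last) + config$task_block_design$n_lead_volumes
}

#' Generate one synthetic BOLD run with its nuisance series
#'
#' Deterministic given the configuration and run labels: the run seed is
#' derived from them, so runs can be generated independently, in any order,
#' with identical results.
#'
#' @param config a [sim_config()].
#' @param subject subject index (1-based).
#' @param tod_idx time-of-day index into `config$tod_labels`.
#' @param day day index.
#' @param condition "rest" or "task".
#' @return list with elements `run` (a [bold_run()]) and `nuisance`
#'   (data.frame with columns tx,ty,tz,rx,ry,rz,csf,wm, one row per volume).
#' @export
simulate_run <- function(config, subject, tod_idx, day, condition = "rest") {
  stopifnot(inherits(config, "sim_config"),
            subject >= 1, subject <= config$n_subjects,
            tod_idx >= 1, tod_idx <= length(config$tod_labels),
            day >= 1, day <= config$n_days)
  condition <- match.arg(condition, c("rest", "task"))
  eff <- study_subject_effects(config)
  set.seed(run_seed(config, subject, tod_idx, day, condition))

  t_len <- if (condition == "rest") config$n_volumes_rest else task_run_volumes(config)
  tr <- config$tr
  gs <- config$grid_shape
  v_tot <- prod(gs)
  lev <- attr(config$region_map, "levels")
  code <- as.vector(config$region_map)

  # shared fluctuations
  osc <- function() {
    if (config$osc_type == "sinusoid") {
      f0 <- mean(config$lowfreq_band)
      config$osc_amp * sin(2 * pi * f0 * (seq_len(t_len) - 1) * tr + stats::runif(1, 0, 2 * pi))
    } else {
      config$osc_amp * band_noise(t_len, tr, config$lowfreq_band)
    }
  }
  g_shared <- osc() / max(config$osc_amp, .Machine$double.eps)  # unit-scale coupling source
  s_reg <- list()
  for (r in GRAY_REGIONS) {
    s <- osc()
    if (r %in% c("thalamus", "cortex-seedtarget") && config$fc_coupling != 0) {
      rho <- config$fc_coupling
      s <- sqrt(1 - rho^2) * s + rho * config$osc_amp * g_shared
    }
    s_reg[[r]] <- s
  }
  amp_factor <- if (condition == "task") config$task_amp_factor else 1
  for (r in names(s_reg)) s_reg[[r]] <- s_reg[[r]] * amp_factor

  csf_sig <- 0.8 * band_noise(t_len, tr, c(0.005, 0.15)) + 0.3 * stats::rnorm(t_len)
  wm_sig <- 0.6 * band_noise(t_len, tr, c(0.005, 0.12)) + 0.3 * stats::rnorm(t_len)

  # motion: smooth random walks, optional injected spikes
  steps <- c(rep(0.02, 3), rep(4e-4, 3))
  motion <- vapply(steps, function(s) cumsum(stats::rnorm(t_len, 0, s)), numeric(t_len))
  colnames(motion) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  if (config$motion_outlier_prob > 0) {
    hit <- which(stats::runif(t_len) < config$motion_outlier_prob)
    for (h in hit) {
      p <- sample.int(6, 1)
      motion[h, p] <- motion[h, p] + 8 * steps[p] * sqrt(t_len) * sign(stats::rnorm(1))
    }
  }
  mp <- rowSums(scale(motion))
  mp <- mp / max(stats::sd(mp), .Machine$double.eps)

  slope <- stats::rnorm(1)
  phase <- stats::runif(1, 0, 2 * pi)
  tt <- seq_len(t_len)
  drift <- config$drift_amp * (slope * (2 * tt / t_len - 1) +
                                 cos(2 * pi * 0.003 * tt * tr + phase))

  eps <- matrix(stats::rnorm(v_tot * t_len), v_tot, t_len)
  eps <- smooth_noise_field(eps, gs, config$smooth_fwhm)

  base <- eff$baseline[subject]
  gsc <- eff$scale[subject]
  leak <- config$nuisance_coupling * (csf_sig + wm_sig + mp)

  # per-region shared time courses (baseline + drift folded in) and
  # per-voxel noise scale; the voxel signal is then assembled in two
  # vectorized operations
  S <- matrix(base + drift, length(lev), t_len, byrow = TRUE)
  scale_code <- rep(config$noise_sd, length(lev))
  for (r in GRAY_REGIONS) {
    rc <- match(r, lev)
    f <- sd_factor(config, r, tod_idx)
    S[rc, ] <- S[rc, ] + gsc * f * s_reg[[r]] + leak
    scale_code[rc] <- gsc * f * config$noise_sd
  }
  S[match("csf", lev), ] <- S[match("csf", lev), ] + csf_sig
  S[match("wm", lev), ] <- S[match("wm", lev), ] + wm_sig
  x <- eps * scale_code[code] + S[code, , drop = FALSE]

  run <- bold_run(array(x, c(gs, t_len)), tr = tr, subject = subject,
                  tod = config$tod_labels[tod_idx], day = day, condition = condition)
  region_mean <- function(r) {
    rows <- x[code == match(r, lev), , drop = FALSE]
    if (nrow(rows) == 0) rep(0, t_len) else colMeans(rows)
  }
  nuis <- data.frame(motion, csf = region_mean("csf"), wm = region_mean("wm"))
  list(run = run, nuisance = nuis)
}

# omission-error rate on the response scale for one subject x tod
omission_rate <- function(config, subject, tod_idx, eff) {
  f <- sd_factor(config, "visual", tod_idx)
  u <- eff$behavior_u[subject]
  if (config$behavior_link == "log") {
    exp(log(config$behavior_rate_midday) + config$behavior_coupling * (f - 1) + u)
  } else {
    max(0.01, config$behavior_rate_midday + config$behavior_coupling * (f - 1) + u)
  }
}

#' Behavioral table for a synthetic study
#'
#' Omission errors per subject x time of day x day, Poisson with a rate
#' linked (log or identity) to the subject's current true visual-region SD
#' factor, plus reaction times with no programmed time-of-day effect.
#' Uses per-cell seeds, so the table is identical whether or not imaging
#' runs are generated.
#'
#' @param config a [sim_config()].
#' @return data.frame: subject, tod, day, omission_errors, reaction_time.
#' @export
simulate_behavior <- function(config) {
  eff <- study_subject_effects(config)
  k <- length(config$tod_labels)
  rows <- expand.grid(day = seq_len(config$n_days), tod_idx = seq_len(k),
                      subject = seq_len(config$n_task_subjects))
  out <- lapply(seq_len(nrow(rows)), function(i) {
    s <- rows$subject[i]; j <- rows$tod_idx[i]; d <- rows$day[i]
    set.seed(run_seed(config, s, j, d, "task", stream = 1L))
    lambda <- omission_rate(config, s, j, eff)
    data.frame(subject = s, tod = config$tod_labels[j], day = d,
               omission_errors = stats::rpois(1, lambda),
               reaction_time = stats::rnorm(1, 450 + 30 * eff$behavior_u[s], 40))
  })
  do.call(rbind, out)
}

#' Session covariates for a synthetic study
#'
#' Physiological measures per subject x time of day x day (heart rate,
#' breathing rate, body temperature, sleepiness with a plausible circadian
#' shape) and subject-level chronotype covariates (MSFsc, wake-up time,
#' sleep debt) with the study's missingness pattern: MSFsc missing for 2
#' subjects, wake-up time for 1, sleep debt for 3 (when enough subjects).
#'
#' @param config a [sim_config()].
#' @return data.frame, one row per subject x tod x day.
#' @export
simulate_covariates <- function(config) {
  set.seed(as.integer((as.double(config$seed) * 31011 + 23) %% 2147483647))
  n <- config$n_subjects
  k <- length(config$tod_labels)
  hour <- suppressWarnings(as.numeric(sub(":.*", "", config$tod_labels)))
  if (anyNA(hour)) hour <- seq(8, 23, length.out = k)
  phase <- 2 * pi * (hour - 16) / 24
  msfsc <- stats::rnorm(n, 4.5, 1)
  wake <- stats::rnorm(n, 7, 0.8)
  debt <- abs(stats::rnorm(n, 1, 0.6))
  if (n >= 10) {
    # the study's missingness pattern: chronotype missing for 2 subjects,
    # wake-up time for 1, sleep debt for 3
    msfsc[sample.int(n, 2)] <- NA
    wake[sample.int(n, 1)] <- NA
    debt[sample.int(n, 3)] <- NA
  }
  rows <- expand.grid(day = seq_len(config$n_days), tod_idx = seq_len(k),
                      subject = seq_len(n))
  j <- rows$tod_idx; s <- rows$subject
  data.frame(
    subject = s, tod = config$tod_labels[j], day = rows$day,
    heart_rate = round(62 + 4 * cos(phase[j]) + stats::rnorm(nrow(rows), 0, 3), 1),
    breathing_rate = round(15 + 1.2 * cos(phase[j]) + stats::rnorm(nrow(rows), 0, 1.2), 1),
    temperature = round(36.6 + 0.25 * cos(phase[j]) + stats::rnorm(nrow(rows), 0, 0.1), 2),
    sleepiness = pmin(9, pmax(1, round(4 - 1.5 * cos(phase[j]) + stats::rnorm(nrow(rows), 0, 1)))),
    chronotype_msfsc = msfsc[s], wake_up_time = wake[s], sleep_debt = debt[s])
}

#' Ground truth record for a synthetic study
#' @param config a [sim_config()].
#' @param null logical; TRUE for a null study.
#' @return list describing every programmed effect, sufficient to score
#'   parameter recovery. Serialized as JSON next to simulated studies.
#' @export
ground_truth <- function(config, null = FALSE) {
  eff <- study_subject_effects(config)
  k <- length(config$tod_labels)
  lev <- attr(config$region_map, "levels")
  sd_scale <- sapply(lev, function(r)
    vapply(seq_len(k), function(j) sd_factor(config, r, j), numeric(1)))
  rownames(sd_scale) <- config$tod_labels
  list(null = null, seed = config$seed, tod_labels = config$tod_labels,
       sd_scale = sd_scale,
       subject_scale = eff$scale, subject_behavior = eff$behavior_u,
       behavior_coupling = config$behavior_coupling,
       behavior_link = config$behavior_link,
       fc_coupling = config$fc_coupling,
       lowfreq_band = config$lowfreq_band,
       expected_rmcorr_sign = sign(config$behavior_coupling))
}

#' Simulate a complete synthetic study
#'
#' Generates every rest (and optionally task) run of the configured design
#' together with nuisance series, the behavioral table, session covariates
#' and the ground-truth record. With `dir` set, runs are written as NIfTI
#' and tables as TSV instead of being held in memory (see
#' [write_study()]); file naming encodes subject/ToD/day/condition.
#'
#' In-memory studies at the full default grid and run length are large;
#' downstream full-scale analyses stream runs with [simulate_run()]
#' instead (see [compute_study_maps()]).
#'
#' @param config a [sim_config()].
#' @param conditions which run conditions to generate.
#' @param dir output directory (NULL returns the study in memory).
#' @return list with `runs` (named list of [bold_run()]), `nuisance`
#'   (named list of data.frames, names matching `runs`), `behavior`,
#'   `covariates`, `truth`, `config`; or, with `dir`, the study manifest.
#' @export
simulate_study <- function(config, conditions = c("rest", "task"), dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  conditions <- match.arg(conditions, c("rest", "task"), several.ok = TRUE)
  runs <- list(); nuis <- list()
  for (s in seq_len(config$n_subjects)) {
    for (j in seq_along(config$tod_labels)) {
      for (d in seq_len(config$n_days)) {
        for (cond in conditions) {
          if (cond == "task" && s > config$n_task_subjects) next
          key <- run_key(s, config$tod_labels[j], d, cond)
          g <- simulate_run(config, s, j, d, cond)
          runs[[key]] <- g$run
          nuis[[key]] <- g$nuisance
        }
      }
    }
  }
  study <- list(runs = runs, nuisance = nuis,
                behavior = simulate_behavior(config),
                covariates = simulate_covariates(config),
                truth = ground_truth(config, null = isTRUE(attr(config, "null"))),
                config = config)
  if (!is.null(dir)) return(write_study(study, dir))
  study
}

#' Null variant of a synthetic study configuration
#'
#' Same generative process with every per-time-of-day SD factor flattened
#' to 1 and the behavior coupling set to 0; the ground truth records the
#' study as null. Used for type-I-error calibration of the group pipeline.
#'
#' @param config a [sim_config()].
#' @return a `sim_config` with all programmed effects removed.
#' @export
null_config <- function(config) {
  k <- length(config$tod_labels)
  config$sd_profile <- list()
  config$behavior_coupling <- 0
  attr(config, "null") <- TRUE
  config
}

#' @rdname null_config
#' @param conditions,dir passed to [simulate_study()].
#' @export
simulate_null_study <- function(config, conditions = "rest", dir = NULL) {
  simulate_study(null_config(config), conditions = conditions, dir = dir)
}

run_key <- function(subject, tod, day, condition) {
  sprintf("sub-%02d_tod-%s_day-%d_%s", subject, gsub(":", "", tod), day, condition)
}
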