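#' Region labels used by the synthetic study generator
#' @export
REGION_LEVELS <- c("background", "cortex", "visual", "somatosensory",
                   "auditory", "thalamus", "cortex-seedtarget", "csf", "wm")

# gray-matter regions: everything analyzed at the group level
GRAY_REGIONS <- c("cortex", "visual", "somatosensory", "auditory",
                  "thalamus", "cortex-seedtarget")

#' Default region map for a synthetic brain
#'
#' Partitions the grid into an ellipsoidal "brain" containing labeled
#' sensory regions (visual, somatosensory, auditory), a central thalamus,
#' a frontal cortical seed-target region, CSF and white-matter
#' compartments, generic cortex, and extracranial background. Regions are
#' axis-aligned boxes intersected with the brain ellipsoid; the layout is
#' a desk-scale stand-in for anatomy, not an atlas.
#'
#' @param grid_shape integer vector of 3 voxel counts.
#' @return integer 3-D array with levels [REGION_LEVELS] (attribute
#'   `levels`); use [region_mask()] to extract logical masks.
#' @export
default_region_map <- function(grid_shape = c(24, 24, 18)) {
  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]
  ctr <- (grid_shape + 1) / 2
  ax <- grid_shape / 2 - 1.2          # semi-axes of the brain ellipsoid
  ix <- slice.index(array(0, grid_shape), 1)
  iy <- slice.index(array(0, grid_shape), 2)
  iz <- slice.index(array(0, grid_shape), 3)
  brain <- ((ix - ctr[1]) / ax[1])^2 + ((iy - ctr[2]) / ax[2])^2 +
    ((iz - ctr[3]) / ax[3])^2 <= 1

  box <- function(xr, yr, zr)
    ix >= xr[1] & ix <= xr[2] & iy >= yr[1] & iy <= yr[2] & iz >= zr[1] & iz <= zr[2]

  # proportional box coordinates so non-default grids stay sensible
  p <- function(frac, n) pmax(1L, pmin(n, round(frac * n)))
  reg <- array(1L, grid_shape)                      # background
  reg[brain] <- 2L                                  # cortex
  put <- function(m, code) reg[m & brain] <<- code
  put(box(p(c(.30, .72), nx), p(c(.82, .97), ny), p(c(.38, .68), nz)), 3L)  # visual (posterior)
  put(box(p(c(.30, .72), nx), p(c(.33, .66), ny), p(c(.80, .93), nz)), 4L)  # somatosensory (superior)
  put(box(p(c(.82, .95), nx), p(c(.38, .66), ny), p(c(.42, .62), nz)), 5L)  # auditory (right lateral)
  put(box(p(c(.55, .72), nx), p(c(.28, .42), ny), p(c(.42, .58), nz)), 8L)  # csf (ventricle analog)
  put(box(p(c(.33, .70), nx), p(c(.45, .72), ny), p(c(.36, .66), nz)), 9L)  # wm (deep)
  put(box(p(c(.42, .60), nx), p(c(.50, .64), ny), p(c(.45, .56), nz)), 6L)  # thalamus (central, inside wm box)
  put(box(p(c(.30, .72), nx), p(c(.06, .20), ny), p(c(.38, .68), nz)), 7L)  # cortex-seedtarget (frontal)
  attr(reg, "levels") <- REGION_LEVELS
  reg
}

#' Logical mask of one or more regions
#' @param region_map integer region array from [default_region_map()].
#' @param regions character vector of region names.
#' @export
region_mask <- function(region_map, regions) {
  lev <- attr(region_map, "levels")
  codes <- match(regions, lev)
  if (anyNA(codes)) stop("unknown region: ", paste(regions[is.na(codes)], collapse = ", "))
  m <- array(region_map %in% codes, dim = dim(region_map))
  m
}

#' Gray-matter analysis mask for a region map
#' @param region_map integer region array.
#' @export
gray_matter_mask <- function(region_map) region_mask(region_map, GRAY_REGIONS)

#' Configuration of a synthetic time-of-day fMRI study
#'
#' Bundles every knob of the generative model: design (subjects, six
#' scan times on consecutive days), acquisition (grid, TR, volumes, task
#' block design), signal composition (band-limited oscillation, white
#' noise, scanner drift, nuisance leakage), the per-region, per-time-of-day
#' multiplicative SD profile that encodes the twilight variance dip, the
#' link from visual-region SD to behavioral lapse rate, and the seed.
#'
#' Defaults reproduce the study design: 14 subjects (9 with the visual
#' detection task), scans at 08:00/11:00/14:00/17:00/20:00/23:00 on two
#' consecutive days, 210-volume rest runs at TR 2 s, task runs of three
#' 1-minute blocks with 11 stimuli each alternating with four 25-s
#' fixation blocks, and a 20% SD reduction at 08:00 and 20:00 confined
#' to the three sensory regions.
#'
#' @param n_subjects number of subjects.
#' @param tod_labels six clock-time labels, strictly ordered.
#' @param n_days days per subject (runs are averaged across days downstream).
#' @param grid_shape voxel counts (x, y, z).
#' @param tr repetition time, seconds.
#' @param n_volumes_rest volumes per rest run, including the leading
#'   saturation volumes discarded by preprocessing.
#' @param task_block_design list: `task_s`, `fixation_s`, `n_task_blocks`,
#'   `n_fixation_blocks`, `n_stimuli_per_block`, `n_lead_volumes`.
#' @param region_map integer region array; built by [default_region_map()]
#'   when NULL.
#' @param sd_profile named list mapping region name to a length-6 vector of
#'   multiplicative SD factors per time of day. Regions not listed get 1.
#'   NULL gives the default twilight dip (`twilight_dip` at positions of
#'   08:00 and 20:00) in visual, somatosensory and auditory regions.
#' @param twilight_dip multiplicative factor applied at 08:00/20:00 when
#'   `sd_profile` is NULL (0.8 = a 20% dip).
#' @param lowfreq_band frequency band (Hz) carrying the oscillatory signal.
#' @param osc_amp amplitude (SD units) of the shared regional oscillation.
#' @param osc_type "bandnoise" (band-limited Gaussian noise, unit SD) or
#'   "sinusoid" (single tone of amplitude `osc_amp`, SD `osc_amp`/sqrt(2)).
#' @param noise_sd voxel-level white-noise SD (> 0).
#' @param drift_amp scanner drift amplitude (linear ramp + slow cosine,
#'   below the high-pass cutoff).
#' @param nuisance_coupling leakage weight of CSF/WM/motion signals into
#'   gray-matter voxels.
#' @param fc_coupling shared-fluctuation weight between the thalamus and
#'   the cortical seed-target region (ground-truth connectivity).
#' @param behavior_coupling slope linking the subject's current visual-region
#'   SD factor to the omission-error rate on the link scale.
#' @param behavior_link "log" (Poisson log link, default) or "identity".
#' @param behavior_rate_midday expected omission errors per task session when
#'   the SD factor is 1 (midday).
#' @param subject_sd SD of the log-normal subject scaling of signal amplitude.
#' @param subject_behavior_sd SD of the subject random effect on the
#'   behavior link scale.
#' @param n_task_subjects subjects (first k) who also perform the task.
#' @param smooth_fwhm FWHM (voxels) of the Gaussian blur applied to the
#'   voxel noise field before scaling; 0 disables smoothing.
#' @param task_amp_factor global oscillation amplitude factor for task runs
#'   relative to rest (< 1 encodes the overall task-related SD decrease).
#' @param motion_outlier_prob per-volume probability of an injected motion
#'   spike (exercises the outlier-count covariate).
#' @param seed integer seed; identical config + seed gives identical studies.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 14,
                       tod_labels = c("08:00", "11:00", "14:00", "17:00", "20:00", "23:00"),
                       n_days = 2,
                       grid_shape = c(24, 24, 18),
                       tr = 2,
                       n_volumes_rest = 210,
                       task_block_design = list(task_s = 60, fixation_s = 25,
                                                n_task_blocks = 3, n_fixation_blocks = 4,
                                                n_stimuli_per_block = 11, n_lead_volumes = 4),
                       region_map = NULL,
                       sd_profile = NULL,
                       twilight_dip = 0.8,
                       lowfreq_band = c(0.01, 0.1),
                       osc_amp = 1,
                       osc_type = c("bandnoise", "sinusoid"),
                       noise_sd = 0.5,
                       drift_amp = 0.2,
                       nuisance_coupling = 0.1,
                       fc_coupling = 0.5,
                       behavior_coupling = 4,
                       behavior_link = c("log", "identity"),
                       behavior_rate_midday = 2.2,
                       subject_sd = 0.1,
                       subject_behavior_sd = 0.3,
                       n_task_subjects = 9,
                       smooth_fwhm = 1.5,
                       task_amp_factor = 0.8,
                       motion_outlier_prob = 0.01,
                       seed = 1) {
  osc_type <- match.arg(osc_type)
  behavior_link <- match.arg(behavior_link)
  stopifnot(n_subjects >= 1, n_days >= 1, length(grid_shape) == 3,
            all(grid_shape >= 1), tr > 0, n_volumes_rest >= 2,
            length(tod_labels) >= 2)
  if (any(duplicated(tod_labels)) || is.unsorted(tod_labels))
    stop("`tod_labels` must be strictly ordered clock times")
  if (noise_sd < 0) stop("`noise_sd` must be non-negative")
  if (any(grid_shape < 3))
    stop("degenerate grid: every dimension must cover the cluster-connectivity footprint (>= 3 voxels)")
  if (is.null(region_map)) region_map <- default_region_map(grid_shape)
  if (!all(dim(region_map) == grid_shape)) stop("region_map shape must match grid_shape")
  k <- length(tod_labels)
  if (is.null(sd_profile)) {
    dip <- rep(1, k)
    dip[tod_labels %in% c("08:00", "20:00")] <- twilight_dip
    sd_profile <- list(visual = dip, somatosensory = dip, auditory = dip)
  }
  lev <- attr(region_map, "levels")
  for (nm in names(sd_profile)) {
    if (!nm %in% lev) stop("sd_profile names must be region labels; got ", nm)
    if (length(sd_profile[[nm]]) != k || any(sd_profile[[nm]] <= 0))
      stop("each sd_profile entry must be a positive vector of length ", k)
  }
  if (lowfreq_band[1] >= lowfreq_band[2] || lowfreq_band[2] > 1 / (2 * tr))
    stop("`lowfreq_band` must be an increasing Hz pair below Nyquist")
  stopifnot(n_task_subjects <= n_subjects, seed == as.integer(seed))
  structure(
    list(n_subjects = n_subjects, tod_labels = tod_labels, n_days = n_days,
         grid_shape = grid_shape, tr = tr, n_volumes_rest = n_volumes_rest,
         task_block_design = task_block_design, region_map = region_map,
         sd_profile = sd_profile, lowfreq_band = lowfreq_band,
         osc_amp = osc_amp, osc_type = osc_type, noise_sd = noise_sd,
         drift_amp = drift_amp, nuisance_coupling = nuisance_coupling,
         fc_coupling = fc_coupling, behavior_coupling = behavior_coupling,
         behavior_link = behavior_link, behavior_rate_midday = behavior_rate_midday,
         subject_sd = subject_sd, subject_behavior_sd = subject_behavior_sd,
         n_task_subjects = n_task_subjects, smooth_fwhm = smooth_fwhm,
         task_amp_factor = task_amp_factor,
         motion_outlier_prob = motion_outlier_prob, seed = as.integer(seed)),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %d subjects x %d ToD x %d days | grid %s | TR %gs, %d rest volumes | seed %d\n",
              x$n_subjects, length(x$tod_labels), x$n_days,
              paste(x$grid_shape, collapse = "x"), x$tr, x$n_volumes_rest, x$seed))
  invisible(x)
}
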