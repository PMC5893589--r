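# Bootstrap power analysis for two-group seed-connectivity differences.

#' Simulate a pool of connectivity-ready epochs
#'
#' Generates short continuous epochs (about 3.5 minutes by default) of the
#' synthetic signal with a programmable thalamus-to-cortical-target
#' coupling, emulating two vigilance states whose thalamocortical
#' connectivity differs. Each epoch is one independent draw.
#'
#' @param config a [sim_config()] (grid, band, noise settings reused).
#' @param n_epochs epochs in the pool.
#' @param fc_coupling thalamus/seed-target shared-fluctuation weight for
#'   this pool (the group difference under study).
#' @param epoch_volumes volumes per epoch (105 at TR 2 s is ~3.5 min).
#' @param label pool label (e.g. "wake", "N1").
#' @param seed integer seed for the pool.
#' @param seed_mask optional logical 3-D seed mask; when given, each epoch
#'   is reduced to its seed connectivity map as it is generated and the raw
#'   run is discarded, keeping large pools in memory.
#' @return list of class `epoch_pool`: label, and either `runs` (list of
#'   [bold_run()]) or `fc` (voxels x epochs matrix of connectivity values).
#' @export
simulate_epoch_pool <- function(config, n_epochs, fc_coupling,
                                epoch_volumes = 105, label = "pool",
                                seed = config$seed, seed_mask = NULL) {
  cfg <- config
  cfg$fc_coupling <- fc_coupling
  cfg$n_volumes_rest <- epoch_volumes
  cfg$seed <- as.integer(seed)
  cfg$sd_profile <- list()   # epochs carry no time-of-day structure
  cfg$n_subjects <- max(n_epochs, cfg$n_subjects)
  gen <- function(e) simulate_run(cfg, subject = e, tod_idx = 1, day = 1,
                                  condition = "rest")$run
  if (is.null(seed_mask)) {
    runs <- lapply(seq_len(n_epochs), gen)
    return(structure(list(label = label, runs = runs, fc = NULL,
                          fc_coupling = fc_coupling,
                          epoch_volumes = epoch_volumes), class = "epoch_pool"))
  }
  fc <- vapply(seq_len(n_epochs), function(e)
    as.vector(seed_fc_map(gen(e), seed_mask)$values),
    numeric(prod(cfg$grid_shape)))
  structure(list(label = label, runs = NULL, fc = fc,
                 fc_coupling = fc_coupling, epoch_volumes = epoch_volumes,
                 grid_shape = cfg$grid_shape), class = "epoch_pool")
}

# two-sample pooled-variance t over rows; groups as column index sets
two_sample_t_rows <- function(M, i1, i2, welch = FALSE) {
  n1 <- length(i1); n2 <- length(i2)
  m1 <- rowMeans(M[, i1, drop = FALSE]); m2 <- rowMeans(M[, i2, drop = FALSE])
  v1 <- rowSums((M[, i1, drop = FALSE] - m1)^2) / (n1 - 1)
  v2 <- rowSums((M[, i2, drop = FALSE] - m2)^2) / (n2 - 1)
  if (welch) {
    se <- sqrt(v1 / n1 + v2 / n2)
  } else {
    sp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp * (1 / n1 + 1 / n2))
  }
  t <- (m1 - m2) / se
  t[se == 0] <- 0
  t
}

#' Bootstrap power analysis for two-group connectivity differences
#'
#' Repeats, `iterations` times: draw `n_per_group` epochs with replacement
#' from each pool, compute each epoch's seed connectivity map, test the
#' group difference with a mass-univariate two-sample two-tailed t-test,
#' and cluster-correct with a group-label permutation maximum-cluster-size
#' null. Returns the voxel-wise proportion of iterations in which the
#' voxel lay in a significant cluster, and the fraction of iterations with
#' at least one significant cluster (empirical power for detecting any
#' difference).
#'
#' Epoch connectivity maps are computed once per pool and resampled, which
#' is equivalent to recomputing them per draw.
#'
#' @param pool_a,pool_b `epoch_pool` objects (e.g. wake and N1 analogs).
#' @param seed_mask logical 3-D seed mask (default: the thalamus of the
#'   config's region map must be supplied explicitly).
#' @param mask logical 3-D analysis mask.
#' @param n_per_group epochs drawn per group per iteration.
#' @param iterations bootstrap iterations (default 1000; < 100 warns).
#' @param primary_alpha cluster-forming (two-tailed) threshold.
#' @param fwe_alpha cluster-level corrected level.
#' @param n_perm nested permutations per iteration (capped for runtime;
#'   the cap is recorded in the output).
#' @param connectivity cluster connectivity.
#' @param seed RNG seed for the bootstrap.
#' @return list of class `bootstrap_power`: `power` (any-cluster),
#'   `proportion_map` ([stat_map()]-like 3-D array of significance
#'   proportions), `iterations`, `n_per_group`, `n_perm`, `seed`,
#'   `n_significant` (per-iteration flags sum).
#' @export
bootstrap_power <- function(pool_a, pool_b, seed_mask, mask,
                            n_per_group = 14, iterations = 1000,
                            primary_alpha = 0.001, fwe_alpha = 0.05,
                            n_perm = 200, connectivity = 18, seed = 1) {
  stopifnot(inherits(pool_a, "epoch_pool"), inherits(pool_b, "epoch_pool"))
  if (iterations < 100)
    warning("fewer than 100 iterations gives unstable power estimates")
  shape <- dim(mask)
  idx <- which(mask)
  pool_fc <- function(pool) {
    if (!is.null(pool$fc)) return(pool$fc[idx, , drop = FALSE])
    vapply(pool$runs, function(run) seed_fc_map(run, seed_mask)$values[idx],
           numeric(length(idx)))
  }
  A <- pool_fc(pool_a)
  B <- pool_fc(pool_b)
  if (n_per_group > ncol(A) || n_per_group > ncol(B))
    message("n_per_group exceeds a pool size; with-replacement draws proceed")
  M <- cbind(A, B)
  na <- ncol(A)
  df <- 2 * n_per_group - 2
  thr <- critical_value("t", df, primary_alpha, tails = "two")
  grid <- rep(NA_real_, prod(shape))
  set.seed(as.integer(seed))
  sig_count <- numeric(length(idx))
  any_sig <- logical(iterations)
  for (it in seq_len(iterations)) {
    da <- sample.int(na, n_per_group, replace = TRUE)
    db <- na + sample.int(ncol(B), n_per_group, replace = TRUE)
    S <- M[, c(da, db), drop = FALSE]
    i1 <- seq_len(n_per_group); i2 <- n_per_group + seq_len(n_per_group)
    tobs <- two_sample_t_rows(S, i1, i2)
    null_sizes <- vapply(seq_len(n_perm), function(p) {
      pe <- sample.int(2 * n_per_group)
      tp <- two_sample_t_rows(S, pe[i1], pe[i2])
      grid[idx] <- abs(tp)
      max_cluster_size(array(grid, shape), thr, connectivity)
    }, integer(1))
    grid[idx] <- abs(tobs)
    tmap <- stat_map(array(grid, shape), "t", df = df)
    tab <- cluster_threshold(tmap, thr, null_sizes, fwe_alpha = fwe_alpha,
                             connectivity = connectivity,
                             min_permutations = min(n_perm, 100))
    if (nrow(tab) > 0) {
      any_sig[it] <- TRUE
      for (mk in cluster_masks(tab)) sig_count <- sig_count + mk[idx]
    }
  }
  prop <- rep(NA_real_, prod(shape))
  prop[idx] <- sig_count / iterations
  structure(list(power = mean(any_sig), proportion_map = array(prop, shape),
                 iterations = iterations, n_per_group = n_per_group,
                 n_perm = n_perm, seed = seed,
                 n_significant = sum(any_sig)),
            class = "bootstrap_power")
}

#' @export
print.bootstrap_power <- function(x, ...) {
  cat(sprintf("<bootstrap_power> any-cluster power = %.3f (%d/%d iterations), n = %d per group, %d nested permutations\n",
              x$power, x$n_significant, x$iterations, x$n_per_group, x$n_perm))
  invisible(x)
}
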