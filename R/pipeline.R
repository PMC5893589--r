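# Orchestration: stream runs through preprocessing and mapping, then the
# group, behavior and mixed-model stages. Runs are generated (or read),
# preprocessed and reduced to maps one at a time, so full-size studies
# never sit in memory as raw 4-D data.

#' Single-subject maps for a whole study, streamed run by run
#'
#' For every subject x time of day x day: generate (or read) the run,
#' preprocess it (discard leading volumes, high-pass filter, nuisance
#' regression, and for task runs block trimming/concatenation), compute the
#' requested voxel-wise map, and accumulate. Motion summaries are collected
#' per run for the confound model.
#'
#' @param config a [sim_config()].
#' @param condition "rest" or "task".
#' @param metric "sd", "alff" or "fc" (thalamic seed).
#' @param preprocess apply the temporal preprocessing pipeline (TRUE for
#'   the standard analysis; FALSE limits preprocessing to discarding the
#'   leading volumes, for reduced harnesses).
#' @param n_discard leading volumes to discard.
#' @param verbose log per-run volume counts.
#' @return list: `maps` (per-subject list of per-ToD day-averaged
#'   [stat_map()]s), `cube_by_day` (mask-voxels x subjects x ToD x days),
#'   `mask`, `mask_idx`, `shape`, `tods`, `motion` (per-run summaries),
#'   `metric`, `condition`, `config`.
#' @export
compute_study_maps <- function(config, condition = "rest", metric = "sd",
                               preprocess = TRUE, n_discard = 4,
                               verbose = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  metric <- match.arg(metric, c("sd", "alff", "fc"))
  condition <- match.arg(condition, c("rest", "task"))
  mask <- gray_matter_mask(config$region_map)
  idx <- which(mask)
  shape <- config$grid_shape
  n <- if (condition == "task") config$n_task_subjects else config$n_subjects
  k <- length(config$tod_labels)
  seed_mask <- if (metric == "fc") region_mask(config$region_map, "thalamus")
  cube <- array(NA_real_, c(length(idx), n, k, config$n_days))
  motion <- list()
  for (s in seq_len(n)) {
    for (j in seq_len(k)) {
      for (d in seq_len(config$n_days)) {
        g <- simulate_run(config, s, j, d, condition)
        run <- g$run
        if (preprocess) {
          run <- preprocess_run(run, g$nuisance, n_discard = n_discard,
                                block_design = config$task_block_design,
                                verbose = verbose)
        } else {
          run <- discard_leading_volumes(run, n_discard)
        }
        m <- switch(metric,
                    sd = voxelwise_sd(run, mask),
                    alff = voxelwise_alff(run, mask, band = config$lowfreq_band),
                    fc = suppressWarnings(seed_fc_map(run, seed_mask, mask)))
        cube[, s, j, d] <- m$values[idx]
        ms <- motion_summaries(trim_nuisance(g$nuisance, n_discard))
        motion[[length(motion) + 1]] <- data.frame(
          subject = s, tod = config$tod_labels[j], day = d, condition = condition,
          motion_amplitude = ms$amplitude, motion_variance = ms$variance,
          motion_outliers = ms$n_outliers)
      }
    }
  }
  day_avg <- rowMeans(cube, dims = 3)
  maps <- lapply(seq_len(n), function(s) {
    lapply(seq_len(k), function(j) {
      v <- rep(NA_real_, prod(shape))
      v[idx] <- day_avg[, s, j]
      stat_map(array(v, shape),
               map_type = switch(metric, sd = "SD", alff = "ALFF", fc = "r"),
               subject = s, tod = config$tod_labels[j], condition = condition)
    })
  })
  list(maps = maps, cube_by_day = cube, mask = mask, mask_idx = idx,
       shape = shape, tods = config$tod_labels, motion = do.call(rbind, motion),
       metric = metric, condition = condition, config = config)
}

#' Cluster-wise values per subject, time of day (and day)
#'
#' Averages the mapped values inside a cluster mask for every cell of the
#' study, mirroring cluster-mean extraction for post-hoc analysis.
#'
#' @param study_maps output of [compute_study_maps()].
#' @param cluster_mask logical 3-D mask (e.g. from [cluster_masks()]).
#' @param by_day keep days separate (for the mixed model) or average them.
#' @return long data.frame: subject, tod, (day,) value.
#' @export
extract_study_values <- function(study_maps, cluster_mask, by_day = FALSE) {
  check_mask(cluster_mask, study_maps$shape)
  sel <- which(as.vector(cluster_mask)[study_maps$mask_idx])
  if (!length(sel)) stop("cluster mask is empty inside the analysis mask")
  cube <- study_maps$cube_by_day
  n <- dim(cube)[2]; k <- dim(cube)[3]; nd <- dim(cube)[4]
  vals <- colMeans(array(cube[sel, , , , drop = FALSE], c(length(sel), n * k * nd)))
  long <- expand.grid(subject = seq_len(n), tod = study_maps$tods,
                      day = seq_len(nd), stringsAsFactors = FALSE)
  long$value <- vals
  if (by_day) return(long)
  agg <- stats::aggregate(value ~ subject + tod, data = long, FUN = mean)
  agg[order(agg$subject, match(agg$tod, study_maps$tods)), ]
}

#' Run the full analysis pipeline on a synthetic study
#'
#' Executes the requested stages in dependency order on a configured
#' synthetic study: single-subject maps ("maps"), group cluster inference
#' with post-hoc tests ("group"), behavioral statistics and brain-behavior
#' repeated-measures correlation ("behavior"), and the confound-adjusted
#' mixed model ("lmm"). Later stages require earlier ones: requesting a
#' stage whose inputs were not computed is an error naming the missing
#' stage.
#'
#' @param config a [sim_config()].
#' @param stages subset of c("maps", "group", "behavior", "lmm").
#' @param n_perm permutations for the cluster-extent null.
#' @param fwe_alpha,primary_alpha inference levels.
#' @param preprocess run full temporal preprocessing per run.
#' @param out_dir optional directory for TSV/JSON report files.
#' @param perm_seed seed for the permutation and any other pipeline
#'   randomness (the study itself is governed by `config$seed`).
#' @param verbose log progress.
#' @return list of class `tod_report` with the stage outputs and a
#'   `provenance` entry (parameters, seeds, permutation counts).
#' @export
run_pipeline <- function(config, stages = c("maps", "group", "behavior", "lmm"),
                         n_perm = 500, fwe_alpha = 0.05, primary_alpha = 0.001,
                         preprocess = TRUE, out_dir = NULL, perm_seed = 1,
                         verbose = FALSE) {
  stages <- match.arg(stages, c("maps", "group", "behavior", "lmm"),
                      several.ok = TRUE)
  need <- function(stage, dep) {
    if (stage %in% stages && !dep %in% stages)
      stop("stage \"", stage, "\" needs the \"", dep, "\" stage to run first")
  }
  need("group", "maps"); need("lmm", "group"); need("behavior", "group")
  report <- list()
  report$provenance <- list(params = config_params(config), n_perm = n_perm,
                            perm_seed = perm_seed, fwe_alpha = fwe_alpha,
                            primary_alpha = primary_alpha,
                            stages = stages, preprocess = preprocess)

  if ("maps" %in% stages) {
    if (verbose) message("maps: streaming rest runs")
    rest <- compute_study_maps(config, "rest", "sd", preprocess = preprocess)
    report$n_mask_voxels <- length(rest$mask_idx)
  }

  if ("group" %in% stages) {
    if (verbose) message("group: RM-ANOVA F-map + permutation cluster inference")
    n <- config$n_subjects; k <- length(config$tod_labels)
    fmap <- rm_anova_map(rest$maps, rest$mask)
    thr <- critical_value("F", fmap$df, primary_alpha)
    set.seed(as.integer(perm_seed))
    null_sizes <- perm_null_rm_anova(rest$maps, rest$mask, thr, n_perm = n_perm)
    clusters <- cluster_threshold(fmap, thr, null_sizes, fwe_alpha = fwe_alpha,
                                  min_permutations = min(n_perm, 500))
    report$f_map <- fmap
    report$clusters <- clusters
    report$cluster_values <- lapply(cluster_masks(clusters), function(mk)
      extract_study_values(rest, mk))
    report$posthoc <- lapply(report$cluster_values, posthoc_paired_tests)
    report$rest_maps <- rest
  }

  if ("behavior" %in% stages) {
    if (verbose) message("behavior: task performance and brain-behavior rmcorr")
    behav <- simulate_behavior(config)
    bav <- stats::aggregate(cbind(omission_errors, reaction_time) ~ subject + tod,
                            data = behav, FUN = mean)
    report$behavior_table <- behav
    report$behavior_anova <- list(
      omissions = behavior_rm_anova(bav, "omission_errors"),
      reaction_time = behavior_rm_anova(bav, "reaction_time"))
    tw_pairs <- list(c("11:00", "08:00"), c("14:00", "08:00"), c("17:00", "08:00"),
                     c("11:00", "20:00"), c("14:00", "20:00"), c("17:00", "20:00"))
    tw_pairs <- Filter(function(p) all(p %in% config$tod_labels), tw_pairs)
    report$behavior_planned <- if (length(tw_pairs))
      planned_paired_tests(bav, tw_pairs, "omission_errors")
    if (length(report$cluster_values)) {
      cv <- report$cluster_values[[1]]
      merged <- merge(cv, bav, by = c("subject", "tod"))
      report$rmcorr <- rmcorr(merged$value, merged$omission_errors, merged$subject)
    }
  }

  if ("lmm" %in% stages) {
    if (verbose) message("lmm: confound-adjusted mixed model")
    roi <- if (nrow(report$clusters) > 0) cluster_masks(report$clusters)[[1]]
           else region_mask(config$region_map, "visual")
    vals <- extract_study_values(rest, roi, by_day = TRUE)
    cov <- simulate_covariates(config)
    tab <- merge(vals, cov, by = c("subject", "tod", "day"))
    tab <- merge(tab, rest$motion[, setdiff(names(rest$motion), "condition")],
                 by = c("subject", "tod", "day"))
    report$lmm <- fit_confound_lmm(
      tab, response = "value",
      fixed = c("heart_rate", "breathing_rate", "temperature", "sleepiness",
                "motion_amplitude", "motion_variance", "motion_outliers",
                "chronotype_msfsc", "wake_up_time", "sleep_debt"),
      interactions = c("chronotype_msfsc", "wake_up_time", "sleep_debt", "day"))
  }

  class(report) <- "tod_report"
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write the report bundle as TSV/JSON files
#' @param report a `tod_report`.
#' @param out_dir output directory.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  prov <- report$provenance
  if (!is.null(report$clusters))
    write_tsv(as.data.frame(report$clusters), file.path(out_dir, "clusters.tsv"))
  if (!is.null(report$posthoc) && length(report$posthoc))
    write_tsv(do.call(rbind, Map(function(tab, i) cbind(cluster = i, tab),
                                 report$posthoc, seq_along(report$posthoc))),
              file.path(out_dir, "posthoc_tests.tsv"))
  if (!is.null(report$behavior_planned))
    write_tsv(report$behavior_planned, file.path(out_dir, "behavior_planned_tests.tsv"))
  summary <- list(
    behavior_anova = report$behavior_anova,
    rmcorr = if (!is.null(report$rmcorr)) unclass(report$rmcorr),
    lmm = if (!is.null(report$lmm)) lmm_summary(report$lmm),
    n_mask_voxels = report$n_mask_voxels)
  write_json_summary(summary, file.path(out_dir, "summary.json"), params = prov)
  invisible(out_dir)
}

#' @export
print.tod_report <- function(x, ...) {
  cat("<tod_report>\n")
  if (!is.null(x$clusters)) {
    cat(sprintf("  %d significant cluster(s)\n", nrow(x$clusters)))
  }
  if (!is.null(x$rmcorr))
    cat(sprintf("  rmcorr(cluster SD, omissions): r = %.3f, p = %.3g\n",
                x$rmcorr$r, x$rmcorr$p))
  if (!is.null(x$lmm)) {
    tod_row <- x$lmm$anova[x$lmm$anova$term == "tod", ]
    if (nrow(tod_row))
      cat(sprintf("  adjusted ToD effect: F(%d, %.1f) = %.2f, p = %.4g\n",
                  tod_row$numDF, tod_row$denDF, tod_row$F, tod_row$p))
  }
  invisible(x)
}
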