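# Group inference across time of day.
#
# FWE control uses a permutation maximum-cluster-size null instead of
# random-field theory: time-of-day labels are permuted within subject for
# the ANOVA F-maps, and subject contrasts are sign-flipped for one-sample
# t-maps. Exact under exchangeability, no smoothness estimation.

#' Upper-tail critical value of a t or F distribution
#'
#' @param family "t" or "F".
#' @param df degrees of freedom: length 1 for t, length 2 for F.
#' @param alpha upper-tail probability in (0, 0.5].
#' @param tails "one" (default) or "two"; for "two" the tail probability is
#'   split (t only — F tests are inherently one-sided here).
#' @return the statistic value cut off by `alpha`.
#' @export
critical_value <- function(family = c("t", "F"), df, alpha = 0.001,
                           tails = c("one", "two")) {
  family <- match.arg(family)
  tails <- match.arg(tails)
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 0.5)
    stop("`alpha` must be in (0, 0.5]")
  if (any(!is.finite(df)) || any(df <= 0)) stop("invalid degrees of freedom")
  a <- if (tails == "two") alpha / 2 else alpha
  if (family == "t") {
    if (length(df) != 1) stop("t needs a single df")
    stats::qt(1 - a, df)
  } else {
    if (length(df) != 2) stop("F needs df = (df1, df2)")
    stats::qf(1 - a, df[1], df[2])
  }
}

#' Partial eta-squared from an F statistic
#'
#' eta_p^2 = F * df1 / (F * df1 + df2).
#'
#' @param F F statistic (>= 0).
#' @param df1,df2 numerator and denominator degrees of freedom.
#' @export
partial_eta_squared <- function(F, df1, df2) {
  if (any(F < 0)) stop("F must be non-negative")
  F * df1 / (F * df1 + df2)
}

#' Repeated-measures Cohen's d (Dunlap)
#'
#' d = t * sqrt(2 * (1 - r) / n), where t is the paired statistic, r the
#' correlation between the two condition vectors and n the number of
#' subjects. Carries the sign of t.
#'
#' @param t paired t statistic.
#' @param r cross-condition correlation, in (-1, 1).
#' @param n number of subjects (>= 2).
#' @export
cohens_d_rm <- function(t, r, n) {
  if (n < 2) stop("n must be >= 2")
  if (abs(r) >= 1) stop("Cohen's d for repeated measures is undefined at |r| = 1")
  t * sqrt(2 * (1 - r) / n)
}

# ---- stacking per-subject per-ToD maps into a masked cube -------------------

# maps: list over subjects, each a list over ToD of stat_map (day-averaged).
# Returns list(cube = V_mask x n x k array, mask_idx, shape, tods)
map_cube <- function(maps, mask) {
  n <- length(maps)
  if (n < 2) stop("need at least 2 subjects")
  k <- length(maps[[1]])
  if (any(vapply(maps, length, 1L) != k))
    stop("incomplete design: every subject needs a map at every time of day (no imputation)")
  shape <- dim(maps[[1]][[1]]$values)
  check_mask(mask, shape)
  idx <- which(mask)
  cube <- array(NA_real_, c(length(idx), n, k))
  for (i in seq_len(n)) for (j in seq_len(k)) {
    v <- maps[[i]][[j]]$values
    if (!identical(dim(v), shape)) stop("map shape mismatch at subject ", i)
    cube[, i, j] <- v[idx]
  }
  if (anyNA(cube)) stop("missing values inside the mask")
  tods <- vapply(maps[[1]], function(m) as.character(m$tod), character(1))
  list(cube = cube, mask_idx = idx, shape = shape, tods = tods)
}

# vectorized one-way repeated-measures ANOVA over the rows of a cube.
# Returns list(F, ss_cond, ss_err, df) given cube V x n x k.
rm_anova_F_cube <- function(cube) {
  dd <- dim(cube); V <- dd[1]; n <- dd[2]; k <- dd[3]
  M <- matrix(cube, V, n * k)
  gm <- rowMeans(M)
  cond_means <- matrix(0, V, k)
  for (j in seq_len(k)) cond_means[, j] <- rowMeans(M[, (j - 1) * n + seq_len(n), drop = FALSE])
  subj_means <- matrix(0, V, n)
  for (i in seq_len(n)) subj_means[, i] <- rowMeans(M[, i + n * (seq_len(k) - 1), drop = FALSE])
  ss_cond <- n * rowSums((cond_means - gm)^2)
  ss_subj <- k * rowSums((subj_means - gm)^2)
  ss_tot <- rowSums((M - gm)^2)
  ss_err <- pmax(0, ss_tot - ss_cond - ss_subj)
  df <- c(k - 1, (k - 1) * (n - 1))
  Fv <- (ss_cond / df[1]) / (ss_err / df[2])
  Fv[ss_cond == 0] <- 0   # no condition variance: F is 0 by convention
  list(F = Fv, df = df)
}

#' Voxel-wise one-way repeated-measures ANOVA F-map
#'
#' Tests the main effect of time of day at every in-mask voxel:
#' F = MS_condition / MS_(condition x subject), df = (k-1, (k-1)(n-1)),
#' assuming homoscedasticity and sphericity. Input maps must be
#' day-averaged and form a complete subject x time-of-day grid.
#'
#' @param maps list over subjects, each a list over times of day of
#'   [stat_map()]s (one day-averaged map per cell).
#' @param mask logical 3-D analysis mask.
#' @return a [stat_map()] of type "F" with `df` set; out-of-mask voxels NA.
#' @export
rm_anova_map <- function(maps, mask) {
  mc <- map_cube(maps, mask)
  res <- rm_anova_F_cube(mc$cube)
  vals <- rep(NA_real_, prod(mc$shape))
  vals[mc$mask_idx] <- res$F
  stat_map(array(vals, mc$shape), "F", df = res$df)
}

# permutation engine: within-subject permutation of time-of-day labels.
# reduce_fun(F_masked_vector) is evaluated per permutation.
rm_anova_permute <- function(cube, n_perm, reduce_fun) {
  dd <- dim(cube); V <- dd[1]; n <- dd[2]; k <- dd[3]
  M <- matrix(cube, V, n * k)
  gm <- rowMeans(M)
  subj_means <- matrix(0, V, n)
  for (i in seq_len(n)) subj_means[, i] <- rowMeans(M[, i + n * (seq_len(k) - 1), drop = FALSE])
  ss_subj <- k * rowSums((subj_means - gm)^2)
  ss_tot <- rowSums((M - gm)^2)
  df <- c(k - 1, (k - 1) * (n - 1))
  out <- vector("list", n_perm)
  P <- matrix(0, n * k, k)
  for (p in seq_len(n_perm)) {
    P[] <- 0
    for (i in seq_len(n)) {
      pi <- sample.int(k)
      P[cbind(i + n * (seq_len(k) - 1), pi)] <- 1 / n
    }
    cond_means <- M %*% P
    ss_cond <- n * (rowSums(cond_means^2) - k * gm^2)
    ss_err <- pmax(.Machine$double.eps, ss_tot - ss_subj - ss_cond)
    Fv <- (pmax(0, ss_cond) / df[1]) / (ss_err / df[2])
    out[[p]] <- reduce_fun(Fv)
  }
  out
}

#' Permutation null of maximum cluster size for the RM-ANOVA F-map
#'
#' Permutes time-of-day labels independently within each subject,
#' recomputes the voxel-wise F-map, thresholds it at `threshold`, and
#' records the maximum suprathreshold cluster size. Uses the current RNG
#' state; seed it for reproducibility.
#'
#' @param maps,mask as in [rm_anova_map()].
#' @param threshold cluster-forming statistic threshold.
#' @param n_perm number of permutations (default 1000).
#' @param connectivity cluster connectivity.
#' @return integer vector of length `n_perm`: max cluster size per
#'   permutation, for [cluster_threshold()].
#' @export
perm_null_rm_anova <- function(maps, mask, threshold, n_perm = 1000,
                               connectivity = 18) {
  mc <- map_cube(maps, mask)
  grid <- rep(NA_real_, prod(mc$shape))
  sizes <- rm_anova_permute(mc$cube, n_perm, function(Fv) {
    grid[mc$mask_idx] <- Fv
    max_cluster_size(array(grid, mc$shape), threshold, connectivity)
  })
  as.integer(unlist(sizes))
}

#' Pairwise post-hoc paired t-tests across all times of day
#'
#' Dependent two-tailed t-tests between every pair of times of day on a
#' per-subject scalar (e.g. cluster-averaged BOLD SD), Bonferroni-corrected
#' over the `m_comparisons` tests, with repeated-measures Cohen's d.
#' Comparison labels are "later-earlier" and the statistic tests
#' later minus earlier.
#'
#' @param values data.frame with columns subject, tod, value (one row per
#'   subject x tod, day-averaged).
#' @param m_comparisons Bonferroni multiplier; default k(k-1)/2.
#' @return data.frame: comparison, mean_diff, t, df, p, p_corrected, d.
#' @export
posthoc_paired_tests <- function(values, m_comparisons = NULL) {
  wide <- table_to_wide(values)
  n <- nrow(wide); k <- ncol(wide)
  if (n < 3) stop("need at least 3 subjects")
  tods <- colnames(wide)
  pairs <- utils::combn(k, 2)
  m <- if (is.null(m_comparisons)) ncol(pairs) else m_comparisons
  rows <- lapply(seq_len(ncol(pairs)), function(q) {
    a <- pairs[1, q]; b <- pairs[2, q]
    paired_row(wide[, b], wide[, a], sprintf("%s-%s", tods[b], tods[a]))
  })
  out <- do.call(rbind, rows)
  out$p_corrected <- pmin(1, m * out$p)
  out
}

# one paired comparison x vs y (x - y); shared by post-hoc and planned tests
paired_row <- function(x, y, label) {
  n <- length(x)
  if (stats::sd(x - y) == 0) {
    # identical condition vectors: no difference to test
    tt <- list(statistic = if (mean(x - y) == 0) 0 else Inf * sign(mean(x - y)),
               parameter = n - 1,
               p.value = if (mean(x - y) == 0) 1 else 0)
  } else {
    tt <- stats::t.test(x, y, paired = TRUE)
  }
  r <- suppressWarnings(stats::cor(x, y))
  d <- if (is.finite(r) && abs(r) < 1)
    cohens_d_rm(unname(tt$statistic), r, n) else NA_real_
  data.frame(comparison = label, mean_diff = mean(x - y),
             t = unname(tt$statistic), df = unname(tt$parameter),
             p = tt$p.value, d = d)
}

table_to_wide <- function(values) {
  stopifnot(all(c("subject", "tod", "value") %in% names(values)))
  tods <- unique(as.character(values$tod))
  subs <- unique(values$subject)
  wide <- matrix(NA_real_, length(subs), length(tods),
                 dimnames = list(subs, tods))
  wide[cbind(match(values$subject, subs), match(as.character(values$tod), tods))] <- values$value
  if (anyNA(wide)) stop("incomplete subject x time-of-day table")
  wide
}

#' Twilight-versus-midday contrast t-map
#'
#' For each subject, the voxel-wise contrast
#' mean(map_08, map_20) - mean(map_11, map_14, map_17); then a one-sample
#' t-test of the contrast against 0 across subjects. Restricted to `roi`.
#' The per-subject contrast maps are attached for sign-flip permutation
#' (see [perm_null_one_sample()]).
#'
#' @param maps list over subjects of lists over times of day of [stat_map()]s.
#' @param roi logical 3-D region of interest (e.g. the visual cluster from
#'   the resting-state analysis).
#' @param twilight,midday time-of-day labels defining the contrast.
#' @return a [stat_map()] of type "t" (df = n - 1) with attribute
#'   `contrasts` (subject x voxel matrix over roi voxels).
#' @export
twilight_contrast_map <- function(maps, roi,
                                  twilight = c("08:00", "20:00"),
                                  midday = c("11:00", "14:00", "17:00")) {
  mc <- map_cube(maps, roi)
  itw <- match(twilight, mc$tods)
  imd <- match(midday, mc$tods)
  if (anyNA(itw) || anyNA(imd))
    stop("twilight/midday labels not found among map times of day")
  con <- rowMeans(mc$cube[, , itw, drop = FALSE], dims = 2) -
    rowMeans(mc$cube[, , imd, drop = FALSE], dims = 2)   # V x n
  tt <- one_sample_t_rows(con)
  vals <- rep(NA_real_, prod(mc$shape))
  vals[mc$mask_idx] <- tt
  out <- stat_map(array(vals, mc$shape), "t", df = ncol(con) - 1)
  attr(out, "contrasts") <- con
  attr(out, "mask_idx") <- mc$mask_idx
  out
}

# vectorized one-sample t over rows of V x n matrix
one_sample_t_rows <- function(con) {
  n <- ncol(con)
  mu <- rowMeans(con)
  s <- sqrt(pmax(0, rowSums((con - mu)^2) / (n - 1)))
  t <- mu / (s / sqrt(n))
  t[s == 0 & mu == 0] <- 0
  t
}

#' Sign-flip permutation null for a one-sample contrast t-map
#'
#' Randomly flips the sign of each subject's contrast map and records the
#' maximum suprathreshold cluster size of the resulting t-map, within the
#' same region the observed map was computed on.
#'
#' @param contrast_map output of [twilight_contrast_map()].
#' @param threshold cluster-forming t threshold.
#' @param n_perm number of sign-flip permutations.
#' @param connectivity cluster connectivity.
#' @param negative test for negative contrasts (threshold -t maps)
#'   in addition to positive; "two" thresholds |t| (default "positive").
#' @return integer vector of max cluster sizes, for [cluster_threshold()].
#' @export
perm_null_one_sample <- function(contrast_map, threshold, n_perm = 1000,
                                 connectivity = 18,
                                 negative = c("positive", "negative", "two")) {
  negative <- match.arg(negative)
  con <- attr(contrast_map, "contrasts")
  idx <- attr(contrast_map, "mask_idx")
  if (is.null(con)) stop("contrast_map lacks per-subject contrasts")
  shape <- dim(contrast_map$values)
  n <- ncol(con)
  grid <- rep(NA_real_, prod(shape))
  vapply(seq_len(n_perm), function(p) {
    fl <- sample(c(-1, 1), n, replace = TRUE)
    tt <- one_sample_t_rows(sweep(con, 2, fl, "*"))
    tt <- switch(negative, positive = tt, negative = -tt, two = abs(tt))
    grid[idx] <- tt
    max_cluster_size(array(grid, shape), threshold, connectivity)
  }, integer(1))
}

#' Minimum-statistic conjunction of contrast maps
#'
#' Voxel-wise minimum across t-maps (global conjunction null): a voxel is
#' conjointly significant where the minimum exceeds the single-contrast
#' threshold. Monotone: adding a map never increases any voxel's value.
#'
#' @param t_maps list of >= 2 [stat_map()]s with identical shape and df.
#' @return a [stat_map()] of the voxel-wise minima.
#' @export
conjunction_map <- function(t_maps) {
  if (length(t_maps) < 2) stop("conjunction needs at least 2 maps")
  shape <- dim(t_maps[[1]]$values)
  for (m in t_maps) {
    if (!identical(dim(m$values), shape)) stop("conjunction maps must share a shape")
  }
  vals <- Reduce(pmin, lapply(t_maps, function(m) m$values))
  stat_map(vals, t_maps[[1]]$map_type, df = t_maps[[1]]$df)
}

#' Spherical region-of-interest mask
#' @param shape grid dimensions.
#' @param center voxel coordinates of the sphere center.
#' @param radius radius in voxels.
#' @export
sphere_mask <- function(shape, center, radius) {
  ix <- slice.index(array(0, shape), 1)
  iy <- slice.index(array(0, shape), 2)
  iz <- slice.index(array(0, shape), 3)
  (ix - center[1])^2 + (iy - center[2])^2 + (iz - center[3])^2 <= radius^2
}

#' Small-volume permutation test within a region of interest
#'
#' Maximum-statistic correction restricted to the ROI voxels: the observed
#' ROI maximum is compared with the permutation distribution of ROI maxima
#' (time-of-day labels permuted within subject).
#'
#' @param maps,mask as in [rm_anova_map()].
#' @param roi logical ROI mask or list(center=, radius=) defining a sphere.
#' @param n_perm permutations.
#' @return list: `max_stat`, `peak` (voxel coords), `p_corrected`,
#'   `significant` (at 0.05), `n_roi_voxels`.
#' @export
small_volume_test <- function(maps, mask, roi, n_perm = 1000) {
  shape <- dim(mask)
  if (is.list(roi) && !is.array(roi)) roi <- sphere_mask(shape, roi$center, roi$radius)
  roi <- roi & mask
  if (!any(roi)) stop("ROI does not intersect the analysis mask")
  mc <- map_cube(maps, mask)
  roi_in_mask <- which(as.vector(roi)[mc$mask_idx])
  obs <- rm_anova_F_cube(mc$cube)
  obs_roi <- obs$F[roi_in_mask]
  peak_local <- roi_in_mask[order(-obs_roi, roi_in_mask)][1]
  peak_lin <- mc$mask_idx[peak_local]
  null_max <- unlist(rm_anova_permute(mc$cube, n_perm, function(Fv) max(Fv[roi_in_mask])))
  p <- mean(null_max >= max(obs_roi))
  list(max_stat = max(obs_roi),
       peak = lin_to_coord(peak_lin, shape),
       p_corrected = p, significant = p < 0.05,
       n_roi_voxels = sum(roi), n_permutations = n_perm)
}

lin_to_coord <- function(i, d) {
  c(((i - 1) %% d[1]) + 1,
    ((i - 1) %/% d[1]) %% d[2] + 1,
    (i - 1) %/% (d[1] * d[2]) + 1)
}

#' Paired comparison of rest versus task BOLD SD
#'
#' Dependent two-tailed paired t-test on per-subject scalars (peak-voxel
#' or cluster-mean BOLD SD averaged over all times of day first), with
#' Bonferroni correction across the number of clusters tested, and
#' repeated-measures Cohen's d.
#'
#' @param rest_values,task_values numeric vectors paired by subject.
#' @param m_comparisons Bonferroni multiplier (number of clusters tested).
#' @return data.frame: mean_diff (rest - task), t, df, p, p_corrected, d.
#' @export
rest_vs_task_sd <- function(rest_values, task_values, m_comparisons = 1) {
  if (length(rest_values) != length(task_values))
    stop("rest and task values must be paired by subject")
  out <- paired_row(rest_values, task_values, "rest-task")
  out$p_corrected <- pmin(1, m_comparisons * out$p)
  out
}
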