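# Single-subject voxel-wise maps: BOLD SD, ALFF, seed connectivity.

#' Voxel-wise standard deviation of the BOLD time series
#'
#' Sample standard deviation (n - 1 denominator) of every in-mask voxel's
#' time series: SD = sqrt(sum((x_i - xbar)^2) / (n - 1)). Out-of-mask
#' voxels are set to NA.
#'
#' @param run a [bold_run()] with at least 2 volumes.
#' @param mask logical 3-D analysis mask (NULL = whole grid).
#' @return a [stat_map()] of type "SD".
#' @export
voxelwise_sd <- function(run, mask = NULL) {
  stopifnot(inherits(run, "bold_run"))
  t_len <- n_volumes(run)
  if (t_len < 2) stop("SD needs at least 2 volumes")
  d <- dim(run$data)
  m <- matrix(run$data, prod(d[1:3]), d[4])
  mu <- rowMeans(m)
  sd_v <- sqrt(pmax(0, (rowSums(m * m) - t_len * mu^2)) / (t_len - 1))
  vals <- apply_mask_vector(sd_v, mask, d[1:3])
  stat_map(array(vals, d[1:3]), "SD", subject = run$subject, tod = run$tod,
           day = run$day, condition = run$condition)
}

apply_mask_vector <- function(v, mask, shape) {
  if (is.null(mask)) return(v)
  check_mask(mask, shape)
  v[!as.vector(mask)] <- NA_real_
  v
}

#' Power spectrum of a time series
#'
#' Two-sided discrete power spectrum P_j = |X_j|^2 / n at frequencies
#' f_j = j / (n * tr), j = 0..n-1. Under this normalization the MEAN of
#' P_j over all n bins equals the mean squared value of the series
#' (Parseval), i.e. the mean squared deviation once the mean is removed.
#'
#' @param x numeric vector.
#' @param tr sampling interval, seconds.
#' @return data.frame with columns `freq`, `power`.
#' @export
power_spectrum <- function(x, tr) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2 / n
  data.frame(freq = (seq_len(n) - 1) / (n * tr), power = p)
}

#' Voxel-wise amplitude of low-frequency fluctuations (ALFF)
#'
#' Mean spectral power within the low-frequency band, computed per voxel
#' from the FFT of the (demeaned) time series. Band edges are inclusive.
#' Note this is mean in-band POWER, not its square root: for a
#' band-limited signal ALFF is therefore proportional to the in-band
#' variance and ordinally consistent with BOLD SD.
#'
#' @param run a [bold_run()].
#' @param mask logical 3-D analysis mask (NULL = whole grid).
#' @param band inclusive frequency band in Hz.
#' @return a [stat_map()] of type "ALFF".
#' @export
voxelwise_alff <- function(run, mask = NULL, band = c(0.01, 0.1)) {
  stopifnot(inherits(run, "bold_run"))
  d <- dim(run$data)
  t_len <- d[4]
  f <- (seq_len(t_len) - 1) / (t_len * run$tr)
  in_band <- f >= band[1] & f <= band[2] & f <= 1 / (2 * run$tr)
  if (sum(in_band) < 2)
    stop("fewer than 2 frequency bins inside the band; run too short or band empty")
  m <- matrix(run$data, prod(d[1:3]), t_len)
  m <- m - rowMeans(m)
  P <- Mod(t(stats::mvfft(t(m))))^2 / t_len
  alff <- rowMeans(P[, in_band, drop = FALSE])
  vals <- apply_mask_vector(alff, mask, d[1:3])
  stat_map(array(vals, d[1:3]), "ALFF", subject = run$subject, tod = run$tod,
           day = run$day, condition = run$condition)
}

#' Seed-based functional connectivity map
#'
#' Pearson correlation between the mean time series over the seed voxels
#' and every in-mask voxel. Voxels with zero temporal variance get r = 0;
#' their count is reported in a warning so unattended null simulations
#' keep running.
#'
#' @param run a [bold_run()].
#' @param seed logical 3-D seed mask (non-empty).
#' @param mask logical 3-D analysis mask (NULL = whole grid).
#' @return a [stat_map()] of type "r".
#' @export
seed_fc_map <- function(run, seed, mask = NULL) {
  stopifnot(inherits(run, "bold_run"))
  d <- dim(run$data)
  check_mask(seed, d[1:3])
  m <- matrix(run$data, prod(d[1:3]), d[4])
  s <- colMeans(m[as.vector(seed), , drop = FALSE])
  r <- row_cor(m, s)
  n_dead <- sum(is.na(r))
  if (n_dead > 0) {
    warning(n_dead, " zero-variance voxel(s); their correlation set to 0")
    r[is.na(r)] <- 0
  }
  vals <- apply_mask_vector(r, mask, d[1:3])
  stat_map(array(vals, d[1:3]), "r", df = d[4] - 2, subject = run$subject,
           tod = run$tod, day = run$day, condition = run$condition)
}

# correlation of every row of m with vector s; NA where a row (or s) is constant
row_cor <- function(m, s) {
  t_len <- ncol(m)
  mc <- m - rowMeans(m)
  sc <- s - mean(s)
  denom_s <- sqrt(sum(sc^2))
  denom_m <- sqrt(rowSums(mc^2))
  num <- as.vector(mc %*% sc)
  out <- num / (denom_m * denom_s)
  out[denom_m == 0 | denom_s == 0] <- NA_real_
  pmin(1, pmax(-1, out))
}

#' Average two same-session maps across days
#'
#' Voxel-wise arithmetic mean of maps acquired at the same time of day on
#' consecutive days. Refuses mismatched map types, time-of-day labels or
#' shapes.
#'
#' @param map_day1,map_day2 [stat_map()] objects.
#' @return the day-averaged [stat_map()].
#' @export
average_days <- function(map_day1, map_day2) {
  stopifnot(inherits(map_day1, "stat_map"), inherits(map_day2, "stat_map"))
  if (map_day1$map_type != map_day2$map_type)
    stop("cannot average maps of different types")
  if (!identical(dim(map_day1$values), dim(map_day2$values)))
    stop("cannot average maps of different shapes")
  if (!is.na(map_day1$tod) && !is.na(map_day2$tod) && map_day1$tod != map_day2$tod)
    stop("day pairing error: maps are from different times of day")
  out <- map_day1
  out$values <- (map_day1$values + map_day2$values) / 2
  out$day <- NA
  out
}

#' Mean (or peak) map value within a cluster
#'
#' @param map a [stat_map()].
#' @param cluster_mask logical 3-D mask of the cluster (non-empty).
#' @param at "mean" for the cluster average, "peak" for the value at
#'   `peak_voxel` (required then).
#' @param peak_voxel length-3 voxel coordinates of the peak.
#' @return scalar.
#' @export
extract_cluster_mean <- function(map, cluster_mask, at = c("mean", "peak"),
                                 peak_voxel = NULL) {
  stopifnot(inherits(map, "stat_map"))
  at <- match.arg(at)
  if (at == "peak") {
    if (is.null(peak_voxel)) stop("`peak_voxel` required for at = \"peak\"")
    return(map$values[peak_voxel[1], peak_voxel[2], peak_voxel[3]])
  }
  check_mask(cluster_mask, dim(map$values))
  mean(map$values[cluster_mask])
}
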