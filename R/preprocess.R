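# Temporal preprocessing. Fixed pipeline order: discard leading volumes ->
# high-pass filter -> nuisance regression -> mask. No spatial realignment
# or normalization: synthetic data are generated aligned.

#' Discard leading volumes of a run
#'
#' Removes the first `n_discard` volumes (magnetic saturation period).
#' Nuisance series must be trimmed in lockstep by the caller; see
#' [trim_nuisance()].
#'
#' @param run a [bold_run()].
#' @param n_discard number of leading volumes to drop (default 4).
#' @return the trimmed [bold_run()].
#' @export
discard_leading_volumes <- function(run, n_discard = 4) {
  stopifnot(inherits(run, "bold_run"), n_discard >= 0)
  t_len <- n_volumes(run)
  if (n_discard >= t_len)
    stop("discarding ", n_discard, " volumes would leave an empty run (t = ", t_len, ")")
  if (n_discard == 0) return(run)
  run$data <- run$data[, , , (n_discard + 1):t_len, drop = FALSE]
  run
}

#' @rdname discard_leading_volumes
#' @param nuisance data.frame of nuisance series, one row per volume.
#' @export
trim_nuisance <- function(nuisance, n_discard = 4) {
  if (n_discard >= nrow(nuisance)) stop("trim would empty the nuisance table")
  if (n_discard == 0) return(nuisance)
  nuisance[(n_discard + 1):nrow(nuisance), , drop = FALSE]
}

butter_hp <- function(tr, cutoff_hz, order) {
  nyq <- 1 / (2 * tr)
  if (cutoff_hz >= nyq) stop("high-pass cutoff (", cutoff_hz, " Hz) must be below Nyquist (", nyq, " Hz)")
  signal::butter(order, cutoff_hz / nyq, type = "high")
}

# zero-phase IIR filtering of every ROW of a matrix (series x time).
# Applied forward then backward with odd (reflected) padding at both ends
# and steady-state initial conditions -- the usual filtfilt construction.
# Row orientation keeps the time recursion on contiguous columns.
filtfilt_rows <- function(b, a, x) {
  n <- ncol(x)
  np <- min(3 * (max(length(a), length(b)) - 1), n - 1)
  pad_head <- 2 * x[, rep(1, np), drop = FALSE] - x[, (np + 1):2, drop = FALSE]
  pad_tail <- 2 * x[, rep(n, np), drop = FALSE] - x[, (n - 1):(n - np), drop = FALSE]
  y <- cbind(pad_head, x, pad_tail)
  y <- iir_rows(b, a, y)
  y <- iir_rows(b, a, y[, ncol(y):1, drop = FALSE])
  y <- y[, ncol(y):1, drop = FALSE]
  y[, (np + 1):(np + n), drop = FALSE]
}

# one forward IIR pass along the rows of x, with steady-state initial
# conditions (input history = first sample, output history = its
# steady-state response), so a constant series maps to an exactly constant
# response from sample one: no start-up transient
iir_rows <- function(b, a, x) {
  b <- b / a[1]; a <- a / a[1]
  k <- length(a); nb <- length(b)
  m <- nrow(x); n <- ncol(x)
  x0 <- x[, 1]
  yss <- x0 * (sum(b) / sum(a))
  p <- nb - 1
  xp <- cbind(matrix(x0, m, p), x)
  u <- b[1] * xp
  if (nb > 1) for (i in 2:nb) {
    u[, i:(n + p)] <- u[, i:(n + p)] + b[i] * xp[, 1:(n + p - i + 1), drop = FALSE]
  }
  u <- u[, (p + 1):(p + n), drop = FALSE]
  q <- k - 1
  if (q == 0) return(u)
  y <- cbind(matrix(yss, m, q), u)
  for (t in (q + 1):(q + n)) {
    acc <- y[, t]
    for (j in seq_len(q)) acc <- acc - a[j + 1] * y[, t - j]
    y[, t] <- acc
  }
  y[, (q + 1):(q + n), drop = FALSE]
}

#' Butterworth high-pass filter
#'
#' Zero-phase (forward-backward) 6th-order Butterworth high-pass with a
#' 0.01 Hz cutoff by default. Accepts a numeric vector, a time x series
#' matrix, or a [bold_run()] (filtered voxel-wise). Zero-phase application
#' squares the one-pass magnitude response and introduces no phase shift
#' relative to the nuisance series.
#'
#' @param x vector, matrix (time in rows), or [bold_run()].
#' @param tr sampling interval in seconds (taken from the run if given one).
#' @param cutoff_hz high-pass cutoff frequency.
#' @param order filter order.
#' @return the filtered object, same type and length as the input.
#' @export
highpass_filter <- function(x, tr = NULL, cutoff_hz = 0.01, order = 6) {
  if (inherits(x, "bold_run")) {
    bf <- butter_hp(x$tr, cutoff_hz, order)
    d <- dim(x$data)
    if (d[4] < 3 * order) stop("run too short to filter (need >= ", 3 * order, " volumes)")
    m <- matrix(x$data, prod(d[1:3]), d[4])
    x$data <- array(filtfilt_rows(bf$b, bf$a, m), d)
    return(x)
  }
  if (is.null(tr)) stop("`tr` is required for vector/matrix input")
  bf <- butter_hp(tr, cutoff_hz, order)
  if (is.matrix(x)) {
    if (nrow(x) < 3 * order) stop("series too short to filter")
    t(filtfilt_rows(bf$b, bf$a, t(x)))
  } else {
    if (length(x) < 3 * order) stop("series too short to filter")
    drop(filtfilt_rows(bf$b, bf$a, matrix(x, nrow = 1)))
  }
}

# remove intercept + linear ramp
detrend_linear <- function(x) {
  t_len <- if (is.matrix(x)) nrow(x) else length(x)
  tt <- seq_len(t_len) - (t_len + 1) / 2
  if (is.matrix(x)) {
    x <- sweep(x, 2, colMeans(x))
    x - outer(tt, colSums(x * tt) / sum(tt^2))
  } else {
    x <- x - mean(x)
    x - tt * sum(x * tt) / sum(tt^2)
  }
}

#' Regress nuisance signals out of a run
#'
#' Builds the 16-regressor design -- six motion parameters, CSF and WM
#' reference series, each with its first backward difference (first element
#' 0) -- linearly detrends every regressor, adds an intercept, and returns
#' the voxel-wise least-squares residuals. Collinear columns are dropped
#' with a warning rather than silently.
#'
#' @param run a [bold_run()].
#' @param nuisance data.frame/matrix with columns tx,ty,tz,rx,ry,rz,csf,wm,
#'   one row per volume of `run`.
#' @return the residual [bold_run()].
#' @export
regress_nuisance <- function(run, nuisance) {
  stopifnot(inherits(run, "bold_run"))
  need <- c("tx", "ty", "tz", "rx", "ry", "rz", "csf", "wm")
  nuisance <- as.matrix(nuisance[, need])
  t_len <- n_volumes(run)
  if (nrow(nuisance) != t_len)
    stop("nuisance series length (", nrow(nuisance), ") does not match run length (", t_len, ")")
  X <- nuisance_design(nuisance)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    warning("nuisance design rank-deficient: dropping ", ncol(X) - qrX$rank,
            " collinear column(s): ", paste(colnames(X)[setdiff(seq_len(ncol(X)), keep)], collapse = ", "))
    qrX <- qr(X[, keep, drop = FALSE])
  }
  d <- dim(run$data)
  Y <- t(matrix(run$data, prod(d[1:3]), d[4]))
  res <- qr.resid(qrX, Y)
  run$data <- array(t(res), d)
  run
}

# intercept + 8 detrended nuisance series + their 8 detrended derivatives
nuisance_design <- function(nuisance) {
  dn <- rbind(0, diff(nuisance))
  colnames(dn) <- paste0("d_", colnames(nuisance))
  X <- cbind(detrend_linear(nuisance), detrend_linear(dn))
  cbind(intercept = 1, X)
}

#' Trim and concatenate the task blocks of a task run
#'
#' Drops the fixation blocks, removes the first `n_discard_per_block`
#' volumes of each task block (carry-over suppression), and concatenates
#' the surviving task volumes in temporal order. The run must already
#' have had its leading saturation volumes discarded, so that volume 1
#' aligns with the onset of the first fixation block.
#'
#' @param run a task [bold_run()].
#' @param block_design task block design list (see [sim_config()]).
#' @param n_discard_per_block volumes dropped at each task-block onset.
#' @return a [bold_run()] holding only the concatenated task volumes.
#' @export
concat_task_blocks <- function(run, block_design, n_discard_per_block = 5) {
  stopifnot(inherits(run, "bold_run"), n_discard_per_block >= 0)
  lay <- task_block_layout(block_design, run$tr)
  if (max(lay$last) > n_volumes(run))
    stop("block design (", max(lay$last), " volumes) exceeds run length (", n_volumes(run), ")")
  keep <- integer(0)
  for (b in which(lay$type == "task")) {
    first <- lay$first[b] + n_discard_per_block
    if (first > lay$last[b])
      stop("task block ", b, " has fewer volumes than n_discard_per_block + 1")
    keep <- c(keep, first:lay$last[b])
  }
  run$data <- run$data[, , , keep, drop = FALSE]
  run
}

#' Optional spatial Gaussian smoothing
#'
#' Separable Gaussian blur of a run (volume-wise) or a 3-D map, for
#' pipelines that smooth before variance mapping. Off by default
#' everywhere: synthetic runs already control their smoothness through the
#' generator.
#'
#' @param x a [bold_run()], [stat_map()] or 3-D array.
#' @param fwhm kernel full width at half maximum, in voxels.
#' @return the smoothed object, same type as the input.
#' @export
gaussian_smooth <- function(x, fwhm) {
  if (fwhm <= 0) return(x)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  blur3 <- function(a) {
    d <- dim(a)
    K1 <- blur_kernel(d[1], sigma); K2 <- blur_kernel(d[2], sigma)
    K3 <- blur_kernel(d[3], sigma)
    t_len <- if (length(d) == 4) d[4] else 1L
    m <- a; dim(m) <- c(d[1], prod(d[-1]))
    m <- K1 %*% m
    dim(m) <- c(d[1], d[2], d[3], t_len)
    m <- aperm(m, c(2, 1, 3, 4))
    dim(m) <- c(d[2], d[1] * d[3] * t_len)
    m <- K2 %*% m
    dim(m) <- c(d[2], d[1], d[3], t_len)
    m <- aperm(m, c(3, 2, 1, 4))
    dim(m) <- c(d[3], d[1] * d[2] * t_len)
    m <- K3 %*% m
    dim(m) <- c(d[3], d[1], d[2], t_len)
    m <- aperm(m, c(2, 3, 1, 4))
    dim(m) <- d
    m
  }
  if (inherits(x, "bold_run")) { x$data <- blur3(x$data); return(x) }
  if (inherits(x, "stat_map")) { x$values <- blur3(x$values); return(x) }
  blur3(x)
}

#' Standard temporal preprocessing of one run
#'
#' The fixed pipeline order: discard leading volumes, high-pass filter,
#' nuisance regression (task runs additionally have their task blocks
#' trimmed and concatenated after the regression step).
#'
#' @param run a [bold_run()].
#' @param nuisance matching nuisance table (full length, untrimmed).
#' @param n_discard leading volumes to drop.
#' @param cutoff_hz,order high-pass settings.
#' @param block_design task block design, required for task runs.
#' @param n_discard_per_block per-block trim for task runs.
#' @param verbose log volume counts before/after each trim.
#' @return the preprocessed [bold_run()].
#' @export
preprocess_run <- function(run, nuisance, n_discard = 4, cutoff_hz = 0.01,
                           order = 6, block_design = NULL,
                           n_discard_per_block = 5, verbose = FALSE) {
  t0 <- n_volumes(run)
  run <- discard_leading_volumes(run, n_discard)
  nuisance <- trim_nuisance(nuisance, n_discard)
  if (verbose) message("discard: ", t0, " -> ", n_volumes(run), " volumes")
  run <- highpass_filter(run, cutoff_hz = cutoff_hz, order = order)
  run <- regress_nuisance(run, nuisance)
  if (run$condition == "task") {
    if (is.null(block_design)) stop("task run requires `block_design`")
    t1 <- n_volumes(run)
    run <- concat_task_blocks(run, block_design, n_discard_per_block)
    if (verbose) message("task blocks: ", t1, " -> ", n_volumes(run), " volumes")
  }
  run
}
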