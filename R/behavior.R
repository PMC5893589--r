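# Behavioral statistics and brain-behavior association.

#' One-way repeated-measures ANOVA on a behavioral variable
#'
#' Tests the time-of-day main effect on a per-subject scalar (omission
#' errors, reaction time, or an extracted cluster value), with Mauchly's
#' test of sphericity and partial eta-squared.
#'
#' @param table long-format data.frame with columns subject, tod, and the
#'   value column; rows must form a complete subject x time-of-day grid
#'   (day-averaged upstream).
#' @param value name of the value column.
#' @return list: F, df1, df2, p, partial_eta_squared, mauchly_p, n, k.
#' @export
behavior_rm_anova <- function(table, value = "value") {
  tab <- data.frame(subject = factor(table$subject),
                    tod = factor(table$tod),
                    value = table[[value]])
  wide <- table_to_wide(data.frame(subject = tab$subject, tod = tab$tod,
                                   value = tab$value))
  n <- nrow(wide); k <- ncol(wide)
  fit <- stats::aov(value ~ tod + Error(subject/tod), data = tab)
  s <- summary(fit)[["Error: subject:tod"]][[1]]
  Fv <- s["tod", "F value"]
  df1 <- s["tod", "Df"]; df2 <- s["Residuals", "Df"]
  p <- s["tod", "Pr(>F)"]
  total_scale <- sum((tab$value - mean(tab$value))^2)
  if (s["tod", "Sum Sq"] < 1e-12 * max(total_scale, .Machine$double.eps)) {
    Fv <- 0; p <- 1   # no condition variance beyond rounding error
  }
  mfit <- stats::lm(wide ~ 1)
  mau <- tryCatch(
    suppressWarnings(
      stats::mauchly.test(mfit, M = ~tod, X = ~1,
                          idata = data.frame(tod = factor(colnames(wide),
                                                          levels = colnames(wide))))),
    error = function(e) NULL)
  list(F = unname(Fv), df1 = unname(df1), df2 = unname(df2), p = unname(p),
       partial_eta_squared = unname(partial_eta_squared(Fv, df1, df2)),
       mauchly_p = if (is.null(mau)) NA_real_ else unname(mau$p.value),
       n = n, k = k)
}

#' Planned pairwise comparisons between selected times of day
#'
#' Dependent two-tailed paired t-tests for a requested list of pairs
#' (typically each twilight session against each midday session), with
#' no multiplicity correction (planned comparisons), mean differences,
#' and repeated-measures Cohen's d. The mean difference and t test the
#' first label minus the second.
#'
#' @param table long-format data.frame with subject, tod, value columns.
#' @param pairs list of character pairs, e.g. `list(c("11:00","08:00"))`.
#' @param value name of the value column.
#' @return data.frame: comparison, mean_diff, t, df, p, d.
#' @export
planned_paired_tests <- function(table, pairs, value = "value") {
  wide <- table_to_wide(data.frame(subject = table$subject, tod = table$tod,
                                   value = table[[value]]))
  tods <- colnames(wide)
  out <- lapply(pairs, function(pr) {
    if (!all(pr %in% tods)) stop("unknown time-of-day label: ",
                                 paste(setdiff(pr, tods), collapse = ", "))
    paired_row(wide[, pr[1]], wide[, pr[2]], sprintf("%s-%s", pr[1], pr[2]))
  })
  do.call(rbind, out)
}

#' Repeated-measures correlation
#'
#' Common within-subject correlation between two repeatedly measured
#' variables, removing between-subject variance: the analysis-of-covariance
#' formulation with subject as a categorical factor and a common slope for
#' x. r carries the sign of the common slope with magnitude
#' sqrt(SS_x / (SS_x + SS_error)); df = n_obs - n_subjects - 1; the p-value
#' is the two-tailed test of the common slope.
#'
#' Subjects contributing fewer than 2 complete observations, or with
#' constant x, are excluded with a warning.
#'
#' @param x,y numeric vectors of repeated measurements.
#' @param subject subject identifier vector, same length.
#' @return list of class `rmcorr_result`: r, df, p, n_obs, n_subjects.
#' @export
rmcorr <- function(x, y, subject) {
  stopifnot(length(x) == length(y), length(x) == length(subject))
  ok <- stats::complete.cases(x, y, subject)
  if (!all(ok)) warning("dropping ", sum(!ok), " incomplete observation(s)")
  x <- x[ok]; y <- y[ok]; subject <- factor(subject[ok])
  bad <- tapply(x, subject, function(v) length(v) < 2 || stats::sd(v) == 0)
  if (any(bad)) {
    warning("excluding ", sum(bad), " subject(s) with < 2 observations or constant x")
    keep <- !(subject %in% names(bad)[bad])
    x <- x[keep]; y <- y[keep]; subject <- droplevels(subject[keep])
  }
  if (nlevels(subject) < 2) stop("rmcorr needs at least 2 subjects")
  full <- stats::lm(y ~ subject + x)
  reduced <- stats::lm(y ~ subject)
  ss_err <- sum(stats::residuals(full)^2)
  ss_x <- sum(stats::residuals(reduced)^2) - ss_err
  slope <- stats::coef(full)[["x"]]
  r <- sign(slope) * sqrt(max(0, ss_x) / (ss_x + ss_err))
  df <- length(x) - nlevels(subject) - 1
  Fv <- if (ss_err <= 0) Inf else (ss_x / 1) / (ss_err / df)
  p <- stats::pf(Fv, 1, df, lower.tail = FALSE)
  structure(list(r = unname(r), df = df, p = unname(p),
                 n_obs = length(x), n_subjects = nlevels(subject)),
            class = "rmcorr_result")
}

#' @export
print.rmcorr_result <- function(x, ...) {
  cat(sprintf("rmcorr: r = %.3f, df = %d, p = %.4g (n_obs = %d, %d subjects)\n",
              x$r, x$df, x$p, x$n_obs, x$n_subjects))
  invisible(x)
}

#' Head-motion summaries of one run
#'
#' Per run: amplitude = mean over the 6 parameters of (max - min);
#' variance = mean per-parameter variance; outliers = number of time
#' points at which any parameter exceeds its own mean +/- 2.5 SD.
#'
#' @param motion matrix/data.frame with 6 motion columns
#'   (tx,ty,tz,rx,ry,rz), one row per volume.
#' @return list: amplitude, variance, n_outliers.
#' @export
motion_summaries <- function(motion) {
  m <- as.matrix(motion[, c("tx", "ty", "tz", "rx", "ry", "rz")])
  rng <- apply(m, 2, function(v) diff(range(v)))
  vv <- apply(m, 2, stats::var)
  mu <- colMeans(m)
  s <- apply(m, 2, stats::sd)
  lo <- matrix(mu - 2.5 * s, nrow(m), 6, byrow = TRUE)
  hi <- matrix(mu + 2.5 * s, nrow(m), 6, byrow = TRUE)
  out_rows <- rowSums(m < lo | m > hi) > 0
  list(amplitude = mean(rng), variance = mean(vv), n_outliers = sum(out_rows))
}
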