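#' A single 4-D BOLD run
#'
#' Container for one functional run: a 4-D array (x, y, z, t) of BOLD
#' values plus acquisition and session metadata. All temporal operations in
#' the package take and return `bold_run` objects so that trimming,
#' filtering and nuisance regression compose without bookkeeping errors.
#'
#' @param data numeric 4-D array, dimensions (x, y, z, t) with t >= 2.
#' @param tr repetition time in seconds (> 0).
#' @param subject subject identifier.
#' @param tod time-of-day label (e.g. "08:00").
#' @param day acquisition day index.
#' @param condition "rest" or "task".
#' @param voxel_size edge length of an isotropic voxel, mm.
#' @return An object of class `bold_run`.
#' @export
bold_run <- function(data, tr, subject = NA, tod = NA, day = NA,
                     condition = "rest", voxel_size = 3) {
  if (!is.array(data) || length(dim(data)) != 4L)
    stop("`data` must be a 4-D array (x, y, z, t)")
  if (dim(data)[4] < 2L) stop("a BOLD run needs at least 2 volumes")
  if (!is.numeric(tr) || tr <= 0) stop("`tr` must be a positive number of seconds")
  condition <- match.arg(condition, c("rest", "task"))
  structure(
    list(data = data, tr = tr, subject = subject, tod = tod, day = day,
         condition = condition, voxel_size = voxel_size),
    class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_run> %dx%dx%d voxels, %d volumes, TR %gs | subject %s, %s, day %s, %s\n",
              d[1], d[2], d[3], d[4], x$tr, x$subject, x$tod, x$day, x$condition))
  invisible(x)
}

n_volumes <- function(run) dim(run$data)[4]

#' A 3-D statistic map
#'
#' One scalar value per voxel: a standard-deviation, ALFF, correlation,
#' t or F map. Inferential maps carry their degrees of freedom.
#'
#' @param values numeric 3-D array.
#' @param map_type one of "SD", "ALFF", "r", "t", "F".
#' @param df degrees of freedom (length 1 for t, length 2 for F), or NULL.
#' @param subject,tod,day,condition provenance labels.
#' @return An object of class `stat_map`.
#' @export
stat_map <- function(values, map_type, df = NULL,
                     subject = NA, tod = NA, day = NA, condition = NA) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3-D array")
  map_type <- match.arg(map_type, c("SD", "ALFF", "r", "t", "F"))
  structure(
    list(values = values, map_type = map_type, df = df,
         subject = subject, tod = tod, day = day, condition = condition),
    class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<stat_map:%s> %dx%dx%d%s\n", x$map_type, d[1], d[2], d[3],
              if (!is.null(x$df)) sprintf(", df = (%s)", paste(x$df, collapse = ", ")) else ""))
  invisible(x)
}

check_mask <- function(mask, shape = NULL) {
  if (!is.array(mask) || length(dim(mask)) != 3L || !is.logical(mask))
    stop("a voxel mask must be a logical 3-D array")
  if (!any(mask)) stop("voxel mask is empty")
  if (!is.null(shape) && !all(dim(mask) == shape))
    stop("mask shape does not match data shape")
  invisible(TRUE)
}

# flatten the spatial dimensions of a run: voxels x time matrix
run_matrix <- function(run, mask = NULL) {
  d <- dim(run$data)
  m <- matrix(run$data, prod(d[1:3]), d[4])
  if (!is.null(mask)) {
    check_mask(mask, d[1:3])
    m <- m[as.vector(mask), , drop = FALSE]
  }
  m
}

# inverse of run_matrix for a full-grid matrix
matrix_to_map <- function(values, shape, ...) {
  stat_map(array(values, dim = shape), ...)
}
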