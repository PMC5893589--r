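# File formats: NIfTI-1 images, TSV tables, JSON summaries.

#' Write / read a BOLD run or statistic map as NIfTI
#'
#' Values and voxel geometry round-trip exactly; run metadata (TR,
#' subject/ToD/day/condition) is carried in the pixdim time slot and the
#' file name, which encodes the labels.
#'
#' @param x a [bold_run()] or [stat_map()].
#' @param path output file (.nii or .nii.gz).
#' @export
write_nifti <- function(x, path) {
  if (inherits(x, "bold_run")) {
    img <- RNifti::asNifti(x$data)
    RNifti::pixdim(img) <- c(rep(x$voxel_size, 3), x$tr)
  } else if (inherits(x, "stat_map")) {
    img <- RNifti::asNifti(x$values)
  } else if (is.array(x)) {
    img <- RNifti::asNifti(x + 0)  # logical masks written as 0/1
  } else stop("cannot write object of class ", paste(class(x), collapse = "/"))
  RNifti::writeNifti(img, path)
  invisible(path)
}

# plain R array, shedding RNifti attributes
nifti_array <- function(img) {
  a <- as.array(img)
  array(as.numeric(a), dim(a))
}

#' @rdname write_nifti
#' @param tr repetition time to attach when reading a 4-D image.
#' @param ... labels (subject, tod, day, condition) for the returned run.
#' @export
read_bold_nifti <- function(path, tr = NULL, ...) {
  img <- RNifti::readNifti(path)
  a <- nifti_array(img)
  if (length(dim(a)) != 4) stop(path, " is not a 4-D image")
  pd <- RNifti::pixdim(img)
  if (is.null(tr)) tr <- if (length(pd) >= 4 && pd[4] > 0) pd[4] else stop("TR not stored; pass `tr`")
  bold_run(a, tr = tr, ..., voxel_size = pd[1])
}

#' @rdname write_nifti
#' @param map_type map type for the returned [stat_map()].
#' @export
read_map_nifti <- function(path, map_type = "SD") {
  a <- nifti_array(RNifti::readNifti(path))
  if (length(dim(a)) == 4 && dim(a)[4] == 1) a <- a[, , , 1]
  stat_map(a, map_type)
}

#' @rdname write_nifti
#' @export
read_mask_nifti <- function(path) {
  a <- nifti_array(RNifti::readNifti(path))
  if (length(dim(a)) == 4 && dim(a)[4] == 1) a <- a[, , , 1]
  array(a != 0, dim(a))
}

#' TSV read/write with fixed conventions (UTF-8, header, tab-separated)
#' @param x data.frame.
#' @param path file path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    fileEncoding = "UTF-8", stringsAsFactors = FALSE)
}

#' JSON summary with embedded provenance
#'
#' Every numeric result file carries the parameter set and seed that
#' produced it.
#'
#' @param x list to serialize.
#' @param path output path.
#' @param params parameter list recorded under `$provenance`.
#' @export
write_json_summary <- function(x, path, params = NULL) {
  if (!is.null(params)) x$provenance <- params
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(path)
}

#' Write a simulated study to disk
#'
#' One NIfTI per run, TSV nuisance tables, the behavior and covariate
#' tables, the ground truth as JSON, and a manifest TSV mapping file paths
#' to (subject, tod, day, condition, kind).
#'
#' @param study output of [simulate_study()] (in-memory form).
#' @param dir output directory, created if needed.
#' @return the manifest data.frame (also written to `manifest.tsv`).
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (key in names(study$runs)) {
    run <- study$runs[[key]]
    bold_path <- file.path(dir, paste0(key, "_bold.nii.gz"))
    nuis_path <- file.path(dir, paste0(key, "_nuisance.tsv"))
    write_nifti(run, bold_path)
    write_tsv(study$nuisance[[key]], nuis_path)
    rows[[length(rows) + 1]] <- data.frame(
      path = c(bold_path, nuis_path), subject = run$subject, tod = run$tod,
      day = run$day, condition = run$condition, kind = c("bold", "nuisance"))
  }
  write_tsv(study$behavior, file.path(dir, "behavior.tsv"))
  write_tsv(study$covariates, file.path(dir, "covariates.tsv"))
  write_json_summary(study$truth, file.path(dir, "ground_truth.json"),
                     params = config_params(study$config))
  manifest <- do.call(rbind, rows)
  manifest <- rbind(manifest,
                    data.frame(path = file.path(dir, c("behavior.tsv", "covariates.tsv")),
                               subject = NA, tod = NA, day = NA, condition = NA,
                               kind = c("behavior", "covariates")))
  write_tsv(manifest, file.path(dir, "manifest.tsv"))
  manifest
}

# flat, serializable view of a sim_config (region map summarized, not dumped)
config_params <- function(config) {
  p <- unclass(config)
  p$region_map <- list(grid_shape = dim(config$region_map),
                       levels = attr(config$region_map, "levels"),
                       n_per_region = as.list(table(factor(
                         attr(config$region_map, "levels")[config$region_map],
                         levels = attr(config$region_map, "levels")))))
  p
}
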