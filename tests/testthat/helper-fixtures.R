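# Shared fixtures: all synthetic, generated in code.

# small, fast study configuration; override any field via ...
tiny_config <- function(...) {
  defaults <- list(n_subjects = 4, n_days = 1, grid_shape = c(10, 10, 8),
                   n_volumes_rest = 40, n_task_subjects = 3,
                   smooth_fwhm = 0, drift_amp = 0, nuisance_coupling = 0,
                   seed = 7)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# a bold_run filled with iid noise
rand_run <- function(shape = c(5, 4, 3), t_len = 30, tr = 2, seed = 1, ...) {
  set.seed(seed)
  bold_run(array(rnorm(prod(shape) * t_len), c(shape, t_len)), tr = tr, ...)
}

# random nuisance table of a given length
rand_nuisance <- function(t_len, seed = 2) {
  set.seed(seed)
  data.frame(tx = cumsum(rnorm(t_len, 0, .02)), ty = cumsum(rnorm(t_len, 0, .02)),
             tz = cumsum(rnorm(t_len, 0, .02)), rx = cumsum(rnorm(t_len, 0, 4e-4)),
             ry = cumsum(rnorm(t_len, 0, 4e-4)), rz = cumsum(rnorm(t_len, 0, 4e-4)),
             csf = rnorm(t_len), wm = rnorm(t_len))
}

# per-subject per-ToD stat_map lists from a voxels x subjects x ToD cube
cube_to_maps <- function(cube, mask, tods = NULL) {
  shape <- dim(mask)
  idx <- which(mask)
  n <- dim(cube)[2]; k <- dim(cube)[3]
  if (is.null(tods)) tods <- sprintf("%02d:00", seq(8, by = 3, length.out = k))
  lapply(seq_len(n), function(s) lapply(seq_len(k), function(j) {
    v <- rep(NA_real_, prod(shape))
    v[idx] <- cube[, s, j]
    stat_map(array(v, shape), "SD", subject = s, tod = tods[j])
  }))
}

# independent sums-of-squares oracle for the one-way RM-ANOVA F
rm_anova_oracle <- function(Y) {  # Y: subjects x conditions
  n <- nrow(Y); k <- ncol(Y)
  gm <- mean(Y)
  ss_cond <- n * sum((colMeans(Y) - gm)^2)
  ss_subj <- k * sum((rowMeans(Y) - gm)^2)
  ss_tot <- sum((Y - gm)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  (ss_cond / (k - 1)) / (ss_err / ((k - 1) * (n - 1)))
}

# brute-force connected components via igraph (independent of the package's
# flood fill)
igraph_cluster_sizes <- function(bin, connectivity) {
  idx <- which(bin)
  if (!length(idx)) return(integer(0))
  d <- dim(bin)
  co <- cbind(((idx - 1) %% d[1]) + 1,
              ((idx - 1) %/% d[1]) %% d[2] + 1,
              (idx - 1) %/% (d[1] * d[2]) + 1)
  edges <- NULL
  if (length(idx) > 1) {
    pr <- utils::combn(seq_along(idx), 2)
    dd <- abs(co[pr[1, ], , drop = FALSE] - co[pr[2, ], , drop = FALSE])
    adj <- switch(as.character(connectivity),
                  "6" = rowSums(dd) == 1,
                  "18" = apply(dd, 1, max) <= 1 & rowSums(dd) <= 2,
                  "26" = apply(dd, 1, max) <= 1)
    edges <- pr[, adj, drop = FALSE]
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(edges) && ncol(edges)) g <- igraph::add_edges(g, as.vector(edges))
  sort(as.integer(igraph::components(g)$csize))
}
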