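# Connected-component machinery for cluster-extent inference.

neighbor_offsets <- function(connectivity = 18) {
  if (!connectivity %in% c(6, 18, 26)) stop("connectivity must be 6, 18 or 26")
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  dist <- abs(g$dx) + abs(g$dy) + abs(g$dz)
  keep <- switch(as.character(connectivity),
                 "6" = dist == 1, "18" = dist <= 2, "26" = rep(TRUE, nrow(g)))
  as.matrix(g[keep, ])
}

#' Label connected suprathreshold components
#'
#' Iterative flood fill over the TRUE voxels of a binary 3-D array using
#' face (6), face+edge (18, the SPM convention and the default) or
#' face+edge+corner (26) neighborhoods.
#'
#' @param bin logical 3-D array.
#' @param connectivity 6, 18 or 26.
#' @return integer 3-D array: 0 outside components, 1..k component labels.
#' @export
label_clusters <- function(bin, connectivity = 18) {
  stopifnot(is.array(bin), length(dim(bin)) == 3L)
  d <- dim(bin)
  off <- neighbor_offsets(connectivity)
  lin_off <- off[, 1] + off[, 2] * d[1] + off[, 3] * d[1] * d[2]
  lab <- array(0L, d)
  idx <- which(bin)
  if (!length(idx)) return(lab)
  in_set <- array(FALSE, d); in_set[idx] <- TRUE
  cur <- 0L
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    lab[start] <- cur
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      x <- ((v - 1) %% d[1]) + 1
      y <- ((v - 1) %/% d[1]) %% d[2] + 1
      z <- (v - 1) %/% (d[1] * d[2]) + 1
      nx <- x + off[, 1]; ny <- y + off[, 2]; nz <- z + off[, 3]
      ok <- nx >= 1 & nx <= d[1] & ny >= 1 & ny <= d[2] & nz >= 1 & nz <= d[3]
      nb <- v + lin_off[ok]
      nb <- nb[in_set[nb] & lab[nb] == 0L]
      if (length(nb)) {
        lab[nb] <- cur
        stack <- c(stack, nb)
      }
    }
  }
  lab
}

# size of the largest suprathreshold component (0 if none)
max_cluster_size <- function(values, threshold, connectivity = 18, mask = NULL) {
  bin <- values > threshold
  bin[is.na(bin)] <- FALSE
  if (!is.null(mask)) bin <- bin & mask
  if (!any(bin)) return(0L)
  lab <- label_clusters(bin, connectivity)
  max(tabulate(lab[lab > 0L]))
}

#' Cluster-extent thresholding with a permutation FWE null
#'
#' Thresholds a statistic map at the cluster-forming value, labels the
#' connected suprathreshold components, and assigns each observed cluster
#' a family-wise-error corrected p-value: the proportion of permutation
#' null datasets whose MAXIMUM cluster size is at least the observed
#' cluster's size. Clusters with p_fwe < `fwe_alpha` survive. Peak voxels
#' are the largest statistic in the cluster, ties broken by lowest linear
#' voxel index so reports are deterministic.
#'
#' @param map a [stat_map()] (t or F).
#' @param threshold cluster-forming statistic threshold (e.g.
#'   `critical_value("F", c(5, 65), 0.001)`).
#' @param null_max_sizes integer vector of maximum cluster sizes under the
#'   permutation null (one entry per permutation), as produced by
#'   [perm_null_rm_anova()] or [perm_null_one_sample()]; alternatively a
#'   list of permutation `stat_map`s / 3-D arrays to reduce.
#' @param fwe_alpha cluster-level corrected significance level.
#' @param connectivity cluster connectivity (6/18/26).
#' @param mask logical 3-D analysis mask (NULL = all finite voxels).
#' @param min_permutations fewer permutations than this is an error.
#' @return object of class `cluster_table`: data.frame with one row per
#'   surviving cluster (size, p_fwe, peak coordinates, peak statistic) and
#'   attributes `all_clusters` (pre-threshold table) and `masks` (list of
#'   member-voxel masks for surviving clusters).
#' @export
cluster_threshold <- function(map, threshold, null_max_sizes,
                              fwe_alpha = 0.05, connectivity = 18,
                              mask = NULL, min_permutations = 500) {
  stopifnot(inherits(map, "stat_map"))
  if (is.list(null_max_sizes)) {
    null_max_sizes <- vapply(null_max_sizes, function(m) {
      v <- if (inherits(m, "stat_map")) m$values else m
      max_cluster_size(v, threshold, connectivity, mask)
    }, integer(1))
  }
  if (length(null_max_sizes) < min_permutations)
    stop("need at least ", min_permutations, " permutations for stable tail estimates; got ",
         length(null_max_sizes))
  vals <- map$values
  bin <- vals > threshold
  bin[is.na(bin)] <- FALSE
  if (!is.null(mask)) bin <- bin & mask
  d <- dim(vals)
  empty <- cluster_table(data.frame(cluster = integer(0), size = integer(0),
                                    p_fwe = numeric(0), peak_x = integer(0),
                                    peak_y = integer(0), peak_z = integer(0),
                                    peak_stat = numeric(0)),
                         all_clusters = NULL, masks = list(),
                         map_type = map$map_type, threshold = threshold,
                         n_permutations = length(null_max_sizes))
  if (!any(bin)) return(empty)
  lab <- label_clusters(bin, connectivity)
  k <- max(lab)
  rows <- lapply(seq_len(k), function(cl) {
    members <- which(lab == cl)
    peak <- members[order(-vals[members], members)][1]
    data.frame(cluster = cl, size = length(members),
               p_fwe = mean(null_max_sizes >= length(members)),
               peak_x = ((peak - 1) %% d[1]) + 1,
               peak_y = ((peak - 1) %/% d[1]) %% d[2] + 1,
               peak_z = (peak - 1) %/% (d[1] * d[2]) + 1,
               peak_stat = vals[peak])
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$size), ]
  keep <- tab$p_fwe < fwe_alpha
  masks <- lapply(tab$cluster[keep], function(cl) array(lab == cl, d))
  out <- tab[keep, , drop = FALSE]
  out$cluster <- seq_len(nrow(out))
  rownames(out) <- NULL
  cluster_table(out, all_clusters = tab, masks = masks,
                map_type = map$map_type, threshold = threshold,
                n_permutations = length(null_max_sizes))
}

cluster_table <- function(df, all_clusters, masks, map_type, threshold, n_permutations) {
  structure(df, all_clusters = all_clusters, masks = masks,
            map_type = map_type, threshold = threshold,
            n_permutations = n_permutations,
            class = c("cluster_table", "data.frame"))
}

#' Member-voxel masks of the surviving clusters
#' @param tab a `cluster_table`.
#' @export
cluster_masks <- function(tab) attr(tab, "masks")

#' @export
print.cluster_table <- function(x, ...) {
  cat(sprintf("<cluster_table> %d significant cluster(s); %s > %.3f, %d permutations\n",
              nrow(x), attr(x, "map_type"), attr(x, "threshold"),
              attr(x, "n_permutations")))
  if (nrow(x)) print.data.frame(x, row.names = FALSE)
  invisible(x)
}
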