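## Density-based clustering of localizations and per-cluster geometry.
##
## DBSCAN with the classical core/border/noise semantics. Core points are
## points with at least min_pts neighbors (the point itself included)
## within radius eps. Clusters are the connected components of the
## core-point graph; a non-core point with at least one core neighbor is a
## border point assigned to the cluster of its lowest-index core neighbor
## (a deterministic tie-break), and everything else is noise (label 0).
## Neighbor search uses an eps-sized grid cell list, so runtime is linear
## in points for bounded local density.

neighbor_lists_ <- function(x, y, eps) {
  n <- length(x)
  nb <- vector("list", n)
  if (n == 0) return(nb)
  cx <- as.integer(floor(x / eps))
  cy <- as.integer(floor(y / eps))
  key <- paste(cx, cy, sep = ":")
  cells <- split(seq_len(n), key)
  lookup <- new.env(hash = TRUE, size = max(16L, length(cells)))
  for (k in names(cells)) assign(k, cells[[k]], envir = lookup)
  eps2 <- eps^2
  for (k in names(cells)) {
    idx <- cells[[k]]
    c0 <- as.integer(strsplit(k, ":", fixed = TRUE)[[1]])
    block_keys <- paste(rep(c0[1] + (-1:1), each = 3), rep(c0[2] + (-1:1), 3),
                        sep = ":")
    cand <- unlist(lapply(block_keys, function(bk) get0(bk, envir = lookup)),
                   use.names = FALSE)
    d2 <- outer(x[idx], x[cand], "-")^2 + outer(y[idx], y[cand], "-")^2
    for (r in seq_along(idx)) {
      nb[[idx[r]]] <- sort(cand[d2[r, ] <= eps2])
    }
  }
  nb
}

#' Density-based (DBSCAN) clustering of a localization table
#'
#' @param table a localization table (or any data.frame with `x`, `y` in nm).
#' @param eps neighborhood radius in nm. The settings used for the
#'   quantitative analyses in this package are eps = 10.8 nm with
#'   min_pts = 15 for adhesion-foci size analysis and eps = 20 nm with
#'   min_pts = 10 for vesicle analysis.
#' @param min_pts minimum number of points (the point itself included)
#'   within `eps` for a core point.
#' @return A `cluster_set` list with
#'   \describe{
#'     \item{labels}{integer per localization; 0 marks noise.}
#'     \item{clusters}{data.frame of per-cluster statistics: `cluster_id`,
#'       `n_locs`, `centroid_x`, `centroid_y`, `max_pairwise_distance`,
#'       `bounding_radius` (all nm).}
#'     \item{eps, min_pts}{the parameters used.}
#'   }
#' @export
dbscan_cluster <- function(table, eps, min_pts) {
  if (!is_pos_num(eps)) stop_arg("eps must be a positive finite number")
  if (!is_count(min_pts) || min_pts < 1) stop_arg("min_pts must be a positive integer")
  if (nrow(table) == 0) stop_arg("cannot cluster an empty table")
  x <- table$x; y <- table$y
  n <- length(x)
  nb <- neighbor_lists_(x, y, eps)
  core <- lengths(nb) >= min_pts
  labels <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != 0L) next
    cid <- cid + 1L
    labels[i] <- cid
    stack <- i
    while (length(stack)) {
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      nbc <- nb[[j]]
      nbc <- nbc[core[nbc] & labels[nbc] == 0L]
      if (length(nbc)) {
        labels[nbc] <- cid
        stack <- c(stack, nbc)
      }
    }
  }
  for (i in which(!core)) {
    cn <- nb[[i]]
    cn <- cn[core[cn]]
    if (length(cn)) labels[i] <- labels[cn[1]]
  }
  structure(list(labels = labels,
                 clusters = cluster_stats_(x, y, labels),
                 eps = eps, min_pts = min_pts),
            class = "cluster_set")
}

cluster_stats_ <- function(x, y, labels) {
  ids <- sort(unique(labels[labels > 0L]))
  if (length(ids) == 0)
    return(data.frame(cluster_id = integer(0), n_locs = integer(0),
                      centroid_x = numeric(0), centroid_y = numeric(0),
                      max_pairwise_distance = numeric(0),
                      bounding_radius = numeric(0)))
  rows <- lapply(ids, function(id) {
    sel <- labels == id
    xs <- x[sel]; ys <- y[sel]
    cx <- mean(xs); cy <- mean(ys)
    data.frame(cluster_id = id, n_locs = sum(sel), centroid_x = cx,
               centroid_y = cy,
               max_pairwise_distance = max_intracluster_distance(xs, ys),
               bounding_radius = sqrt(max((xs - cx)^2 + (ys - cy)^2)))
  })
  do.call(rbind, rows)
}

#' Maximum intracluster distance (cluster diameter)
#'
#' The maximum Euclidean distance between any two member localizations.
#' For large clusters the diameter is computed on the convex hull, which
#' gives the identical result to the exhaustive O(n^2) maximum.
#'
#' @param x,y member coordinates in nm.
#' @return The diameter in nm (0 for a single point or coincident points).
#' @export
max_intracluster_distance <- function(x, y) {
  n <- length(x)
  if (n == 0) stop_arg("empty cluster has no diameter")
  if (n == 1) return(0)
  if (n > 80) {
    h <- unique(chull(x, y))
    if (length(h) >= 2) { x <- x[h]; y <- y[h] }
  }
  max(dist(cbind(x, y)))
}
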