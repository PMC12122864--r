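# Independent oracles and small fixture builders used across tests.

# Brute-force density clustering from the definition: neighbor counts from
# the full distance matrix, clusters = connected components of the
# core-point graph (via igraph), border points assigned to the cluster of
# their lowest-index core neighbor. Independent of the package's grid
# implementation.
brute_dbscan <- function(x, y, eps, min_pts) {
  n <- length(x)
  D <- as.matrix(dist(cbind(x, y)))
  adj <- D <= eps
  core <- rowSums(adj) >= min_pts
  labels <- integer(n)
  if (any(core)) {
    ci <- which(core)
    sub <- adj[ci, ci, drop = FALSE]
    g <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected",
                                             diag = FALSE)
    comp <- igraph::components(g)$membership
    labels[ci] <- comp
    for (i in which(!core)) {
      nb <- which(adj[i, ] & core)
      if (length(nb)) labels[i] <- labels[nb[1]]
    }
  }
  labels
}

# Do two label vectors describe the same partition (noise label 0 fixed,
# cluster ids up to permutation)?
same_partition <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  if (!all((a == 0) == (b == 0))) return(FALSE)
  key_a <- as.integer(factor(a[a != 0], levels = unique(a[a != 0])))
  key_b <- as.integer(factor(b[b != 0], levels = unique(b[b != 0])))
  all(key_a == key_b)
}

# Localization table of repeated noisy observations of fixed sites.
sim_site_table <- function(sites_x, sites_y, n_frames, sigma, photons = 2000,
                           seed = 1) {
  withr::with_seed(seed, {
    k <- length(sites_x)
    frame <- rep(seq_len(n_frames) - 1L, each = k)
    sx <- rep(sites_x, n_frames)
    sy <- rep(sites_y, n_frames)
    data.frame(frame = frame,
               x = sx + rnorm(length(sx), 0, sigma),
               y = sy + rnorm(length(sy), 0, sigma),
               photons = photons,
               sigma_loc_x = sigma, sigma_loc_y = sigma,
               site_id = rep(seq_len(k) - 1L, n_frames))
  })
}

# Monte-Carlo oracle for the alternating renewal process: simulates the
# dark/bright alternation directly (independently of simulate_kinetics)
# and returns the event count for one site.
mc_renewal_events <- function(T_end, tau_dark, tau_bright) {
  t <- 0; k <- 0L
  repeat {
    t <- t + rexp(1, 1 / tau_dark)
    if (t >= T_end) break
    k <- k + 1L
    t <- t + rexp(1, 1 / tau_bright)
    if (t >= T_end) break
  }
  k
}

# Pixel-integrated Gaussian spot image (expected counts), used to build
# synthetic frames for the spot fitter.
spot_image <- function(d, x0, y0, photons, bg, sigma_px) {
  e <- 0:d
  dx <- pnorm((e[-1] - x0) / sigma_px) - pnorm((e[-(d + 1)] - x0) / sigma_px)
  dy <- pnorm((e[-1] - y0) / sigma_px) - pnorm((e[-(d + 1)] - y0) / sigma_px)
  photons * outer(dy, dx) + bg
}
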