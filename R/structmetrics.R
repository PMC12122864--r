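## Distance analytics: projected two-Gaussian pair distances, cross-section
## profiles, and RESI super-localization averaging.

principal_axis_ <- function(pts) {
  v <- eigen(cov(pts), symmetric = TRUE)$vectors[, 1]
  # deterministic sign: positive x-component (positive y on ties)
  if (v[1] < 0 || (v[1] == 0 && v[2] < 0)) v <- -v
  v
}

# Two-Gaussian vs one-Gaussian histogram fit with F-ratio model selection.
two_gaussian_hist_fit_ <- function(v, nbins = NULL, alpha = 0.05) {
  n <- length(v)
  if (is.null(nbins)) {
    nbins <- tryCatch(grDevices::nclass.FD(v), error = function(e) 16L)
    nbins <- max(nbins, 24L)
  }
  h <- graphics::hist(v, breaks = nbins, plot = FALSE)
  dat <- data.frame(xm = h$mids, yc = h$counts)
  bw <- diff(h$breaks)[1]
  m <- mean(v); s <- sd(v)
  fit1 <- tryCatch(
    minpack.lm::nlsLM(yc ~ a * exp(-(xm - mu)^2 / (2 * sg^2)), data = dat,
                      start = list(a = max(h$counts), mu = m, sg = s),
                      lower = c(0, min(v) - s, bw / 10),
                      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  fit2 <- tryCatch(
    minpack.lm::nlsLM(
      yc ~ a1 * exp(-(xm - mu1)^2 / (2 * s1^2)) +
           a2 * exp(-(xm - mu2)^2 / (2 * s2^2)),
      data = dat,
      start = list(a1 = max(h$counts), a2 = max(h$counts),
                   mu1 = m - s, mu2 = m + s, s1 = s / 2, s2 = s / 2),
      lower = c(0, 0, min(v) - s, min(v) - s, bw / 10, bw / 10),
      control = minpack.lm::nls.lm.control(maxiter = 400)),
    error = function(e) NULL)
  rss1 <- if (is.null(fit1)) Inf else sum(stats::residuals(fit1)^2)
  rss2 <- if (is.null(fit2)) Inf else sum(stats::residuals(fit2)^2)
  nb <- nrow(dat)
  p_value <- if (!is.finite(rss1)) 0 else if (!is.finite(rss2)) 1 else {
    df2 <- nb - 6
    if (df2 < 1 || rss2 <= 0) 0 else {
      Fstat <- ((rss1 - rss2) / 3) / (rss2 / df2)
      pf(max(Fstat, 0), 3, df2, lower.tail = FALSE)
    }
  }
  # a resolved pair must also be bimodal: the fitted sum must dip between
  # the two means, otherwise the second component merely reshapes one peak
  bimodal <- FALSE
  if (!is.null(fit2)) {
    p <- stats::coef(fit2)
    f2v <- function(z) p[["a1"]] * exp(-(z - p[["mu1"]])^2 / (2 * p[["s1"]]^2)) +
      p[["a2"]] * exp(-(z - p[["mu2"]])^2 / (2 * p[["s2"]]^2))
    mid <- (p[["mu1"]] + p[["mu2"]]) / 2
    bimodal <- f2v(mid) < 0.98 * min(f2v(p[["mu1"]]), f2v(p[["mu2"]]))
  }
  list(fit1 = fit1, fit2 = fit2, rss1 = rss1, rss2 = rss2,
       p_value = p_value, hist = h,
       two_preferred = p_value <= alpha && bimodal)
}

#' Pair distance from a projected two-Gaussian fit
#'
#' Projects the localizations onto an axis (by default the first principal
#' axis of the point set, sign fixed toward positive x), histograms the
#' projected positions, and fits a sum of two Gaussians by least squares.
#' The pair distance is the separation of the fitted means. Model
#' selection against a single Gaussian uses a residual F-ratio at level
#' `alpha`; when the single Gaussian is preferred the pair is unresolved
#' and an error of class `paintquant_unresolved` (carrying the single-mode
#' SD as `sigma_single`) is thrown. A point set with exactly two distinct
#' projected positions is treated as the degenerate noise-free case and
#' returns their exact separation.
#'
#' @param table a localization table (or data.frame with `x`, `y` in nm)
#'   holding the localizations of one pair.
#' @param projection `"principal_axis"` or `"given_axis"`.
#' @param axis unit vector `c(ux, uy)` when `projection = "given_axis"`.
#' @param nbins histogram bin count (default: Freedman-Diaconis, at
#'   least 24).
#' @param alpha F-test level for preferring the two-Gaussian model.
#' @return A `pair_distance_result` list: `distance` (nm), `means`,
#'   `sds`, `amplitudes`, `n_locs`, `rss`, `p_value`, `axis`.
#' @export
pair_distance <- function(table, projection = c("principal_axis", "given_axis"),
                          axis = NULL, nbins = NULL, alpha = 0.05) {
  projection <- match.arg(projection)
  pts <- cbind(table$x, table$y)
  if (nrow(pts) < 20) stop_arg("need at least 20 localizations, got %d", nrow(pts))
  u <- if (projection == "principal_axis") principal_axis_(pts) else {
    if (is.null(axis)) stop_arg("axis required for given_axis projection")
    axis / sqrt(sum(axis^2))
  }
  t <- as.vector(scale(pts, scale = FALSE) %*% u)
  uq <- sort(unique(round(t, 9)))
  if (length(uq) <= 2) {
    if (length(uq) < 2)
      stop(errorCondition("pair unresolved: all projected positions coincide",
                          sigma_single = 0,
                          class = c("paintquant_unresolved", "error", "condition")))
    return(structure(list(distance = diff(uq), means = uq, sds = c(0, 0),
                          amplitudes = as.vector(table(factor(round(t, 9), levels = uq))),
                          n_locs = nrow(pts), rss = 0, p_value = 0, axis = u),
                     class = "pair_distance_result"))
  }
  sel <- two_gaussian_hist_fit_(t, nbins = nbins, alpha = alpha)
  if (!sel$two_preferred) {
    sg <- if (is.null(sel$fit1)) sd(t) else unname(stats::coef(sel$fit1)[["sg"]])
    stop(errorCondition(
      sprintf("pair unresolved: single Gaussian preferred (p = %.3g, sigma = %.3g nm)",
              sel$p_value, sg),
      sigma_single = sg,
      class = c("paintquant_unresolved", "error", "condition")))
  }
  p <- stats::coef(sel$fit2)
  ord <- order(c(p[["mu1"]], p[["mu2"]]))
  means <- c(p[["mu1"]], p[["mu2"]])[ord]
  structure(list(distance = diff(means), means = means,
                 sds = abs(c(p[["s1"]], p[["s2"]]))[ord],
                 amplitudes = c(p[["a1"]], p[["a2"]])[ord],
                 n_locs = nrow(pts), rss = sel$rss2, p_value = sel$p_value,
                 axis = u),
            class = "pair_distance_result")
}

#' Cross-section profile along a segment
#'
#' Selects localizations inside the rectangle of the given width around
#' the segment, projects them onto the axis perpendicular to the segment,
#' and histograms the perpendicular offsets. Optionally fits a double
#' Gaussian to report the peak-to-peak distance (e.g. between the two
#' walls of a microtubule); if the two-peak model is not preferred the
#' profile is returned without a pair fit.
#'
#' @param table a localization table.
#' @param p0,p1 segment endpoints `c(x, y)` in nm.
#' @param width rectangle width in nm (perpendicular extent).
#' @param nbins histogram bin count for the profile (default
#'   Freedman-Diaconis, at least 15).
#' @param fit whether to attempt the double-Gaussian fit.
#' @param alpha F-test level for the pair fit.
#' @return A `cross_section_profile` list: `mids`, `counts` (profile
#'   histogram, nm on the perpendicular axis, zero at the segment line),
#'   `n_locs`, and `pair` (NULL, or a list with `peak_to_peak`, `means`,
#'   `sds`).
#' @export
cross_section <- function(table, p0, p1, width, nbins = NULL, fit = TRUE,
                          alpha = 0.05) {
  seg <- c(p1[1] - p0[1], p1[2] - p0[2])
  L <- sqrt(sum(seg^2))
  if (L <= 0 || width <= 0) stop_arg("segment length and width must be positive")
  u <- seg / L
  vperp <- c(-u[2], u[1])
  rx <- table$x - p0[1]; ry <- table$y - p0[2]
  along <- rx * u[1] + ry * u[2]
  perp <- rx * vperp[1] + ry * vperp[2]
  sel <- along >= 0 & along <= L & abs(perp) <= width / 2
  v <- perp[sel]
  if (length(v) == 0)
    return(structure(list(mids = numeric(0), counts = integer(0), n_locs = 0L,
                          pair = NULL),
                     class = "cross_section_profile"))
  if (is.null(nbins)) {
    nbins <- tryCatch(grDevices::nclass.FD(v), error = function(e) 15L)
    nbins <- max(nbins, 15L)
  }
  h <- graphics::hist(v, breaks = nbins, plot = FALSE)
  pair <- NULL
  if (fit && length(v) >= 20 && length(unique(round(v, 9))) > 2) {
    s2 <- two_gaussian_hist_fit_(v, nbins = nbins, alpha = alpha)
    if (s2$two_preferred && !is.null(s2$fit2)) {
      p <- stats::coef(s2$fit2)
      ord <- order(c(p[["mu1"]], p[["mu2"]]))
      means <- c(p[["mu1"]], p[["mu2"]])[ord]
      pair <- list(peak_to_peak = diff(means), means = means,
                   sds = abs(c(p[["s1"]], p[["s2"]]))[ord],
                   p_value = s2$p_value)
    }
  }
  structure(list(mids = h$mids, counts = h$counts, n_locs = length(v),
                 pair = pair),
            class = "cross_section_profile")
}

#' RESI super-localization by grouping and inverse-variance averaging
#'
#' Within each imaging round, localization groups belonging to one target
#' are identified by density clustering; each group with at least
#' `group_min` members is collapsed into a single super-localization at
#' the inverse-variance-weighted mean position, with per-axis precision
#' `sigma_resi = (sum sigma_i^-2)^(-1/2)`. For K equal-precision
#' localizations this is exactly `sigma / sqrt(K)`. Results are pooled
#' across rounds.
#'
#' @param tables a list of localization tables, one per round (rounds are
#'   taken from a `round_id` column when present, else from list order).
#' @param eps,min_pts density-clustering parameters for grouping.
#' @param group_min minimum localizations per group before averaging
#'   (default 5).
#' @return A `resi_result` data.frame: `x`, `y`, `sigma_resi_x`,
#'   `sigma_resi_y`, `sigma_resi` (mean of the two axes), `k`
#'   (contributing localizations), `round_id`.
#' @export
resi_combine <- function(tables, eps, min_pts = 10, group_min = 5) {
  if (inherits(tables, "data.frame")) tables <- list(tables)
  if (length(tables) == 0) stop_arg("need at least one round")
  out <- list()
  for (r in seq_along(tables)) {
    tab <- tables[[r]]
    if (is.null(tab) || nrow(tab) == 0) {
      warning(sprintf("round %d is empty; skipped", r))
      next
    }
    validate_loc_table(tab)
    rid <- if ("round_id" %in% names(tab)) tab$round_id[1] else r - 1L
    cs <- dbscan_cluster(tab, eps = eps, min_pts = min_pts)
    for (id in cs$clusters$cluster_id) {
      sel <- cs$labels == id
      if (sum(sel) < group_min) next
      wx <- 1 / tab$sigma_loc_x[sel]^2
      wy <- 1 / tab$sigma_loc_y[sel]^2
      srx <- 1 / sqrt(sum(wx)); sry <- 1 / sqrt(sum(wy))
      out[[length(out) + 1]] <- data.frame(
        x = sum(wx * tab$x[sel]) / sum(wx),
        y = sum(wy * tab$y[sel]) / sum(wy),
        sigma_resi_x = srx, sigma_resi_y = sry,
        sigma_resi = (srx + sry) / 2,
        k = sum(sel), round_id = rid)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(x = numeric(0), y = numeric(0), sigma_resi_x = numeric(0),
               sigma_resi_y = numeric(0), sigma_resi = numeric(0),
               k = integer(0), round_id = integer(0))
  class(res) <- c("resi_result", "data.frame")
  res
}
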