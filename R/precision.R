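## Localization-precision summaries: CRLB-mode sigma_SMLM, NeNA, and the
## 2.35-sigma resolution rule.

#' Summarize localization precision (sigma_SMLM)
#'
#' The reported precision is the average of the per-axis modes of the
#' per-localization precision distributions: the mode of `sigma_loc_x`
#' and of `sigma_loc_y` are estimated from Freedman-Diaconis histograms
#' (ties broken toward the smaller value) and averaged.
#'
#' @param table a localization table.
#' @return A `precision_summary` list: `sigma_x_mode`, `sigma_y_mode`,
#'   `sigma_smlm` (all nm), `n_locs`.
#' @export
summarize_precision <- function(table) {
  validate_loc_table(table)
  if (nrow(table) == 0) stop_arg("cannot summarize an empty table")
  sx <- hist_mode_(table$sigma_loc_x)
  sy <- hist_mode_(table$sigma_loc_y)
  structure(list(sigma_x_mode = sx, sigma_y_mode = sy,
                 sigma_smlm = (sx + sy) / 2, n_locs = nrow(table)),
            class = "precision_summary")
}

#' Resolution estimate from a localization precision
#'
#' Full-width-at-half-maximum rule: resolution = 2.35 * sigma.
#'
#' @param sigma localization precision in nm (non-negative).
#' @return `2.35 * sigma` in nm.
#' @export
resolution_estimate <- function(sigma) {
  if (any(!is.finite(sigma)) || any(sigma < 0)) stop_arg("sigma must be non-negative")
  2.35 * sigma
}

adjacent_frame_nn_ <- function(table, cap) {
  by_frame <- split(seq_len(nrow(table)), table$frame)
  fr <- as.integer(names(by_frame))
  d_all <- numeric(0)
  for (k in seq_along(fr)) {
    nxt <- match(fr[k] + 1L, fr)
    if (is.na(nxt)) next
    a <- by_frame[[k]]; b <- by_frame[[nxt]]
    d2 <- outer(table$x[a], table$x[b], "-")^2 + outer(table$y[a], table$y[b], "-")^2
    dmin <- sqrt(apply(d2, 1, min))
    d_all <- c(d_all, dmin[dmin <= cap])
  }
  d_all
}

#' NeNA localization-precision estimate
#'
#' Nearest-neighbor analysis: for every localization, the distance to its
#' nearest neighbor in the next frame (capped at `max_pair_distance`) is
#' collected. Repeated localizations of the same molecule in adjacent
#' frames produce a 2D displacement whose distance density is
#' `p(d) = d/(2 sigma^2) * exp(-d^2 / (4 sigma^2))` for per-localization
#' precision sigma; unrelated neighbors contribute an approximately linear
#' background `B * d`. The histogram of distances is fit with the sum of
#' both components and the fitted sigma is returned. When most of the fit
#' mass sits in the background component the estimate is flagged
#' unreliable.
#'
#' @param table a localization table spanning at least two frames.
#' @param max_pair_distance nearest-neighbor distance cap in nm
#'   (default 150).
#' @param min_pairs minimum number of pairs required (default 100).
#' @return A `nena_result` list: `sigma_nena` (nm), `n_pairs`,
#'   `reliable` (logical), `fit` (amplitudes and background), `hist`.
#' @export
nena <- function(table, max_pair_distance = 150, min_pairs = 100) {
  validate_loc_table(table)
  if (length(unique(table$frame)) < 2) stop_arg("table must span at least two frames")
  d <- adjacent_frame_nn_(table, max_pair_distance)
  if (length(d) < min_pairs)
    stop_arg("too few adjacent-frame nearest-neighbor pairs: %d (need %d)",
             length(d), min_pairs)
  # degenerate: essentially zero displacements (noise-free repeated sites)
  if (diff(range(d)) < 1e-9 || sqrt(mean(d^2)) < 1e-6) {
    return(structure(list(sigma_nena = sqrt(mean(d^2)) / 2, n_pairs = length(d),
                          reliable = TRUE, fit = NULL, hist = NULL),
                     class = "nena_result"))
  }
  h <- hist_fd_(d, min_bins = 12)
  dat <- data.frame(xm = h$mids, yc = h$counts)
  s0 <- max(sqrt(mean(d^2)) / 2, 1e-4)
  a0 <- max(h$counts) * 2 * s0 * exp(0.5)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      yc ~ A * xm / (2 * s^2) * exp(-xm^2 / (4 * s^2)) + B * xm,
      data = dat, start = list(A = a0, s = s0, B = 0),
      lower = c(0, 1e-6, 0),
      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  if (is.null(fit)) stop_arg("NeNA distance-model fit did not converge")
  p <- stats::coef(fit)
  corr_mass <- sum(p[["A"]] * h$mids / (2 * p[["s"]]^2) * exp(-h$mids^2 / (4 * p[["s"]]^2)))
  bg_mass <- sum(p[["B"]] * h$mids)
  structure(list(sigma_nena = p[["s"]], n_pairs = length(d),
                 reliable = corr_mass > bg_mass,
                 fit = list(A = p[["A"]], B = p[["B"]],
                            rss = sum(stats::residuals(fit)^2)),
                 hist = h),
            class = "nena_result")
}
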