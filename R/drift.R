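## Drift trajectories, application, and fiducial-based correction.

#' Drift trajectories
#'
#' A drift trajectory is a data.frame with one row per frame and columns
#' `frame` (0-based), `dx`, `dy` (nm displacement of the sample relative
#' to frame 0; frame 0 has zero displacement by convention).
#'
#' @param n_frames number of frames.
#' @param vx,vy drift velocity in nm per frame.
#' @return A drift trajectory data.frame.
#' @export
make_linear_drift <- function(n_frames, vx, vy) {
  f <- seq_len(n_frames) - 1L
  data.frame(frame = f, dx = vx * f, dy = vy * f)
}

#' @rdname make_linear_drift
#' @param step_sd per-frame random-walk step standard deviation in nm.
#' @param seed integer seed.
#' @export
make_random_walk_drift <- function(n_frames, step_sd, seed = 1L) {
  f <- seq_len(n_frames) - 1L
  with_seed_(seed, {
    data.frame(frame = f,
               dx = cumsum(c(0, rnorm(n_frames - 1, 0, step_sd))),
               dy = cumsum(c(0, rnorm(n_frames - 1, 0, step_sd))))
  })
}

#' Apply a drift trajectory to a localization table
#'
#' Shifts every localization by the displacement of its frame; all other
#' columns are unchanged.
#'
#' @param table a localization table.
#' @param drift a drift trajectory (see [make_linear_drift()]).
#' @return The shifted table.
#' @export
apply_drift <- function(table, drift) {
  validate_loc_table(table)
  stopifnot(all(c("frame", "dx", "dy") %in% names(drift)))
  if (nrow(table) == 0) return(table)
  idx <- match(table$frame, drift$frame)
  if (anyNA(idx))
    stop_arg("frame index outside the drift trajectory (frames %d..%d covered)",
             min(drift$frame), max(drift$frame))
  table$x <- table$x + drift$dx[idx]
  table$y <- table$y + drift$dy[idx]
  table
}

#' Fiducial-based drift correction
#'
#' Estimates per-frame drift as the mean displacement of fiducial
#' localizations relative to each fiducial's own time-average position,
#' averaged over fiducials, linearly interpolated over frames without
#' fiducial localizations, and smoothed with a centered moving average.
#' The smoothed trajectory (anchored to zero at the first frame) is then
#' subtracted from all localizations.
#'
#' @param table a localization table.
#' @param fiducials either a data.frame of circular regions with columns
#'   `x`, `y`, `r` (nm), or an integer vector of `site_id`s identifying
#'   fiducial localizations in a synthetic table.
#' @param smoothing_window centered moving-average window in frames.
#' @param n_frames total number of frames (default: max frame + 1).
#' @return A list with `table` (corrected) and `drift` (the estimated
#'   trajectory, a data.frame of `frame`, `dx`, `dy`).
#' @export
correct_drift <- function(table, fiducials, smoothing_window = 100,
                          n_frames = NULL) {
  validate_loc_table(table)
  if (is.null(n_frames)) n_frames <- max(table$frame) + 1L
  frames <- seq_len(n_frames) - 1L
  if (is.data.frame(fiducials)) {
    stopifnot(all(c("x", "y", "r") %in% names(fiducials)))
    groups <- lapply(seq_len(nrow(fiducials)), function(i) {
      which((table$x - fiducials$x[i])^2 + (table$y - fiducials$y[i])^2 <=
              fiducials$r[i]^2)
    })
  } else {
    if (!("site_id" %in% names(table)))
      stop_arg("table has no site_id column; pass fiducial regions instead")
    groups <- lapply(as.integer(fiducials), function(s) which(table$site_id == s))
  }
  groups <- groups[lengths(groups) > 0]
  if (length(groups) == 0) stop_arg("no fiducial localizations found")
  cover <- length(unique(table$frame[unlist(groups)])) / n_frames
  if (cover < 0.9)
    warning(sprintf("fiducials cover only %.0f%% of frames; drift estimate may be poor",
                    100 * cover))
  acc_x <- matrix(NA_real_, length(groups), n_frames)
  acc_y <- matrix(NA_real_, length(groups), n_frames)
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    fx <- tapply(table$x[idx], table$frame[idx], mean)
    fy <- tapply(table$y[idx], table$frame[idx], mean)
    fidx <- as.integer(names(fx)) + 1L
    acc_x[g, fidx] <- fx - mean(table$x[idx])
    acc_y[g, fidx] <- fy - mean(table$y[idx])
  }
  dx <- colMeans(acc_x, na.rm = TRUE)
  dy <- colMeans(acc_y, na.rm = TRUE)
  fill_ <- function(v) {
    ok <- is.finite(v)
    if (!any(ok)) stop_arg("no usable fiducial frames")
    if (all(ok)) return(v)
    approx(frames[ok], v[ok], xout = frames, rule = 2)$y
  }
  dx <- runmean_(fill_(dx), smoothing_window)
  dy <- runmean_(fill_(dy), smoothing_window)
  dx <- dx - dx[1]
  dy <- dy - dy[1]
  drift <- data.frame(frame = frames, dx = dx, dy = dy)
  corrected <- table
  idx <- match(table$frame, frames)
  corrected$x <- table$x - dx[idx]
  corrected$y <- table$y - dy[idx]
  list(table = corrected, drift = drift)
}
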