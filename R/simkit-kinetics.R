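## DNA-PAINT blinking kinetics and localization emission.
##
## Imager binding at one docking site is modeled as an alternating renewal
## process: exponential dark dwells with mean tau_dark = 1/(k_on * c) and
## exponential bright dwells with mean tau_bright, starting in the dark
## state. The mean dark time is what qPAINT inverts into a molecule count.

#' Binding-kinetics parameters
#'
#' @param tau_bright mean bright dwell time in seconds.
#' @param k_on imager association rate constant (per molar per second).
#' @param imager_conc imager concentration in molar.
#' @return A list with `tau_bright`, `k_on`, `imager_conc` and the derived
#'   mean dark time `tau_dark = 1/(k_on * imager_conc)` in seconds.
#'   The defaults (0.5 s, 2.2e6 /M/s, 1 nM) put the single-site dark time
#'   at about 454.5 s, i.e. a unit qPAINT index of 0.0022 per second.
#' @export
kinetics_params <- function(tau_bright = 0.5, k_on = 2.2e6, imager_conc = 1e-9) {
  if (!is_pos_num(tau_bright) || !is_pos_num(k_on) || !is_pos_num(imager_conc))
    stop_arg("kinetics parameters must be positive and finite")
  tau_dark <- 1 / (k_on * imager_conc)
  if (!is.finite(tau_dark) || tau_dark <= 0) stop_arg("derived tau_dark is not finite")
  structure(list(tau_bright = tau_bright, k_on = k_on,
                 imager_conc = imager_conc, tau_dark = tau_dark),
            class = "kinetics_params")
}

#' Acquisition configuration
#'
#' @param n_frames number of camera frames.
#' @param exposure frame integration time in seconds.
#' @param pixel_size camera pixel size in nm (default 108).
#' @param fov field of view `c(width, height)` in nm.
#' @param mean_photons expected photons collected from one imager over one
#'   fully bright frame.
#' @param background_rate expected background photons per pixel per frame.
#' @param psf_sigma Gaussian PSF standard deviation in nm.
#' @param detection_min_photons localizations below this photon count are
#'   not detected.
#' @return A list of acquisition parameters with derived total duration
#'   `duration = n_frames * exposure`.
#' @export
acq_config <- function(n_frames = 18000, exposure = 0.3, pixel_size = 108,
                       fov = c(20000, 20000), mean_photons = 2000,
                       background_rate = 1, psf_sigma = 130,
                       detection_min_photons = 50) {
  if (!is_count(n_frames) || n_frames < 1) stop_arg("n_frames must be a positive integer")
  if (!is_pos_num(exposure) || !is_pos_num(pixel_size) || !is_pos_num(mean_photons) ||
      !is_pos_num(psf_sigma))
    stop_arg("exposure, pixel_size, mean_photons, psf_sigma must be positive")
  if (background_rate < 0 || detection_min_photons < 0)
    stop_arg("background_rate and detection_min_photons must be non-negative")
  structure(list(n_frames = as.integer(n_frames), exposure = exposure,
                 pixel_size = pixel_size, fov = fov,
                 mean_photons = mean_photons, background_rate = background_rate,
                 psf_sigma = psf_sigma,
                 detection_min_photons = detection_min_photons,
                 duration = n_frames * exposure),
            class = "acq_config")
}

#' Simulate imager binding events for every docking site
#'
#' Each site runs an independent alternating renewal process: exponential
#' dark intervals with mean `tau_dark`, exponential bright intervals with
#' mean `tau_bright`, starting in the dark state and truncated at the
#' acquisition end. Fiducial sites are treated as always bright.
#'
#' @param model an `emitter_model`.
#' @param kinetics a [kinetics_params()] list.
#' @param acq an [acq_config()] list.
#' @param seed integer seed.
#' @return A `binding_events` object: a list with one two-column matrix
#'   (`t_start`, `t_end`, seconds) per site, plus the acquisition duration
#'   as attribute `duration`.
#' @export
simulate_kinetics <- function(model, kinetics, acq, seed = 1L) {
  validate_emitter_model(model)
  stopifnot(inherits(kinetics, "kinetics_params"), inherits(acq, "acq_config"))
  T_end <- acq$duration
  n <- nrow(model)
  ev <- with_seed_(seed, {
    lapply(seq_len(n), function(i) {
      if (model$role[i] == "fiducial")
        return(matrix(c(0, T_end), 1, 2, dimnames = list(NULL, c("t_start", "t_end"))))
      starts <- numeric(0); ends <- numeric(0)
      t <- 0
      repeat {
        t <- t + rexp(1, rate = 1 / kinetics$tau_dark)
        if (t >= T_end) break
        dur <- rexp(1, rate = 1 / kinetics$tau_bright)
        starts <- c(starts, t)
        ends <- c(ends, min(t + dur, T_end))
        t <- t + dur
        if (t >= T_end) break
      }
      matrix(c(starts, ends), ncol = 2, dimnames = list(NULL, c("t_start", "t_end")))
    })
  })
  structure(ev, duration = T_end, class = "binding_events")
}

new_loc_table <- function(frame = integer(0), x = numeric(0), y = numeric(0),
                          photons = numeric(0), sigma_loc_x = numeric(0),
                          sigma_loc_y = numeric(0), site_id = NULL,
                          round_id = NULL, cluster_id = NULL) {
  df <- data.frame(frame = as.integer(frame), x = as.double(x), y = as.double(y),
                   photons = as.double(photons),
                   sigma_loc_x = as.double(sigma_loc_x),
                   sigma_loc_y = as.double(sigma_loc_y))
  if (!is.null(site_id)) df$site_id <- as.integer(site_id)
  if (!is.null(round_id)) df$round_id <- as.integer(round_id)
  if (!is.null(cluster_id)) df$cluster_id <- as.integer(cluster_id)
  df
}

loc_required_cols <- c("frame", "x", "y", "photons", "sigma_loc_x", "sigma_loc_y")

validate_loc_table <- function(table) {
  miss <- setdiff(loc_required_cols, names(table))
  if (length(miss))
    stop_arg("localization table is missing column(s): %s", paste(miss, collapse = ", "))
  if (nrow(table)) {
    if (any(!is.finite(table$x)) || any(!is.finite(table$y)))
      stop_arg("localization positions must be finite")
    if (any(table$photons <= 0)) stop_arg("photon counts must be positive")
    if (any(table$sigma_loc_x <= 0) || any(table$sigma_loc_y <= 0))
      stop_arg("localization precisions must be positive")
  }
  invisible(table)
}

#' Emit a localization table from binding events
#'
#' For every frame overlapping a bright interval of a site, the photon
#' count is Poisson with mean `mean_photons` times the fractional overlap
#' of the bright interval with the frame. Frames reaching the detection
#' threshold yield one localization at the true site position plus
#' isotropic Gaussian error with sigma = `psf_sigma / sqrt(photons)`, the
#' photon-limited localization precision recorded per axis. Fiducial sites
#' are localized in every frame with `fiducial_photon_factor` times the
#' normal photon budget.
#'
#' @param events a `binding_events` object from [simulate_kinetics()].
#' @param model the `emitter_model` the events were simulated for.
#' @param acq an [acq_config()] list.
#' @param seed integer seed.
#' @param fiducial_photon_factor photon multiplier for fiducial sites.
#' @return A localization table (data.frame) with columns `frame` (0-based),
#'   `x`, `y` (nm), `photons`, `sigma_loc_x`, `sigma_loc_y` (nm), `site_id`.
#' @export
emit_localizations <- function(events, model, acq, seed = 1L,
                               fiducial_photon_factor = 10) {
  stopifnot(inherits(events, "binding_events"), inherits(acq, "acq_config"))
  validate_emitter_model(model)
  if (length(events) != nrow(model))
    stop_arg("events and model disagree on the number of sites")
  exp_t <- acq$exposure
  thr <- max(acq$detection_min_photons, 1)
  with_seed_(seed, {
    site_frames <- vector("list", length(events))
    site_mu <- vector("list", length(events))
    for (i in seq_along(events)) {
      m <- events[[i]]
      if (nrow(m) == 0) next
      f0 <- pmax(0L, as.integer(floor(m[, 1] / exp_t)))
      f1 <- pmin(acq$n_frames - 1L,
                 as.integer(floor((m[, 2] - 1e-12) / exp_t)))
      keep <- f1 >= f0
      if (!any(keep)) next
      fr <- unlist(mapply(seq.int, f0[keep], f1[keep], SIMPLIFY = FALSE))
      # fractional overlap of the bright interval with each frame
      ts <- rep(m[keep, 1], f1[keep] - f0[keep] + 1L)
      te <- rep(m[keep, 2], f1[keep] - f0[keep] + 1L)
      frac <- (pmin(te, (fr + 1) * exp_t) - pmax(ts, fr * exp_t)) / exp_t
      mu <- acq$mean_photons * frac
      if (model$role[i] == "fiducial") mu <- mu * fiducial_photon_factor
      # merge multiple events landing in one frame
      agg <- rowsum(mu, fr)
      site_frames[[i]] <- as.integer(rownames(agg))
      site_mu[[i]] <- as.vector(agg)
    }
    fr <- unlist(site_frames)
    if (is.null(fr) || length(fr) == 0) return(new_loc_table(site_id = integer(0)))
    mu <- unlist(site_mu)
    sid <- rep(seq_along(events) - 1L, lengths(site_frames))
    photons <- rpois(length(mu), mu)
    keep <- photons >= thr
    fr <- fr[keep]; sid <- sid[keep]; photons <- photons[keep]
    sig <- acq$psf_sigma / sqrt(photons)
    xi <- model$x[sid + 1L] + rnorm(length(fr), 0, sig)
    yi <- model$y[sid + 1L] + rnorm(length(fr), 0, sig)
    ord <- order(fr, sid)
    new_loc_table(frame = fr[ord], x = xi[ord], y = yi[ord],
                  photons = photons[ord], sigma_loc_x = sig[ord],
                  sigma_loc_y = sig[ord], site_id = sid[ord])
  })
}

#' One-call DNA-PAINT simulation
#'
#' Convenience wrapper: simulates binding kinetics, emits localizations,
#' optionally applies a drift trajectory, and returns the table together
#' with a ground-truth record (site coordinates, per-site event and
#' localization counts) for recovery scoring.
#'
#' @inheritParams simulate_kinetics
#' @param drift optional drift trajectory from [make_linear_drift()] or
#'   [make_random_walk_drift()].
#' @param fiducial_photon_factor photon multiplier for fiducial sites.
#' @return A list with `locs` (localization table) and `truth` (list:
#'   `sites` data.frame with per-site event counts, `seed`, acquisition and
#'   kinetics parameters).
#' @export
simulate_paint <- function(model, kinetics, acq, seed = 1L, drift = NULL,
                           fiducial_photon_factor = 10) {
  ev <- simulate_kinetics(model, kinetics, acq, seed = derive_seed(seed, 1))
  locs <- emit_localizations(ev, model, acq, seed = derive_seed(seed, 2),
                             fiducial_photon_factor = fiducial_photon_factor)
  if (!is.null(drift)) locs <- apply_drift(locs, drift)
  truth <- list(
    sites = cbind(as.data.frame(model),
                  n_events = vapply(ev, nrow, integer(1)),
                  n_locs = as.vector(table(factor(locs$site_id,
                                                  levels = seq_len(nrow(model)) - 1L)))),
    seed = seed,
    kinetics = unclass(kinetics),
    acquisition = unclass(acq)
  )
  list(locs = locs, truth = truth)
}

#' Render simulated camera frames
#'
#' Produces a small synthetic camera stack (photon counts) from binding
#' events: each bright site contributes a pixel-integrated 2D Gaussian PSF
#' scaled by its expected photons for the frame, a constant background is
#' added, and shot noise is drawn per pixel. Intended for exercising the
#' spot fitter at desk scale, not for full-field rendering.
#'
#' @inheritParams emit_localizations
#' @param frames_subset optional 0-based frame indices to render.
#' @return A 3D array `[row, col, frame]` of photon counts; pixels are
#'   `pixel_size` nm, x maps to columns and y to rows, origin at the
#'   field-of-view corner.
#' @export
simulate_frames <- function(events, model, acq, seed = 1L, frames_subset = NULL) {
  stopifnot(inherits(events, "binding_events"), inherits(acq, "acq_config"))
  validate_emitter_model(model)
  px <- acq$pixel_size
  ncol_px <- ceiling(acq$fov[1] / px)
  nrow_px <- ceiling(acq$fov[2] / px)
  frames <- if (is.null(frames_subset)) seq_len(acq$n_frames) - 1L else as.integer(frames_subset)
  exp_t <- acq$exposure
  with_seed_(seed, {
    out <- array(0, dim = c(nrow_px, ncol_px, length(frames)))
    xe <- (0:ncol_px) * px
    ye <- (0:nrow_px) * px
    for (k in seq_along(frames)) {
      f <- frames[k]
      img <- matrix(acq$background_rate, nrow_px, ncol_px)
      for (i in seq_along(events)) {
        m <- events[[i]]
        if (nrow(m) == 0) next
        ov <- pmin(m[, 2], (f + 1) * exp_t) - pmax(m[, 1], f * exp_t)
        frac <- sum(pmax(ov, 0)) / exp_t
        if (frac <= 0) next
        n_exp <- acq$mean_photons * frac
        dx <- pnorm((xe[-1] - model$x[i]) / acq$psf_sigma) -
          pnorm((xe[-length(xe)] - model$x[i]) / acq$psf_sigma)
        dy <- pnorm((ye[-1] - model$y[i]) / acq$psf_sigma) -
          pnorm((ye[-length(ye)] - model$y[i]) / acq$psf_sigma)
        img <- img + n_exp * outer(dy, dx)
      }
      out[, , k] <- matrix(rpois(length(img), img), nrow_px, ncol_px)
    }
    out
  })
}
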