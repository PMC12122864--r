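test_that("dark times are the frame gaps between bright runs, censored ends excluded", {
  r <- extract_dark_times(c(1, 2, 3, 10, 20), exposure = 0.3)
  expect_equal(r$dark_intervals, c(1.8, 2.7))
  expect_equal(r$n_bright_periods, 3L)
  expect_true(r$countable)
  # duplicates and within-run multiplicity do not matter
  r2 <- extract_dark_times(c(3, 1, 2, 2, 10, 10, 20, 1), exposure = 0.3)
  expect_equal(r2$dark_intervals, r$dark_intervals)
  # single bright run: no complete dark interval
  r3 <- extract_dark_times(5:9, exposure = 0.3)
  expect_false(r3$countable)
  expect_equal(r3$n_intervals, 0L)
  # intervals are positive multiples of the exposure
  expect_true(all(abs(r$dark_intervals / 0.3 - round(r$dark_intervals / 0.3)) < 1e-9))
})

test_that("dark-time fitting recovers an exponential mean by either method", {
  rec_const <- structure(list(dark_intervals = rep(2.4, 5), n_intervals = 5L,
                              countable = TRUE), class = "dark_time_record")
  expect_equal(fit_dark_time(rec_const, "mle_mean")$tau_d, 2.4)
  set.seed(6)
  tt <- rexp(500, rate = 0.0022)
  rec <- structure(list(dark_intervals = tt, n_intervals = 500L, countable = TRUE),
                   class = "dark_time_record")
  se <- (1 / 0.0022) / sqrt(500)
  f_cdf <- fit_dark_time(rec, "cdf_lsq")
  f_mle <- fit_dark_time(rec, "mle_mean")
  expect_lt(abs(f_cdf$tau_d - 1 / 0.0022), 3 * se)
  expect_lt(abs(f_mle$tau_d - 1 / 0.0022), 3 * se)
  expect_lt(abs(f_cdf$tau_d / f_mle$tau_d - 1), 0.10)
  expect_equal(f_mle$xi * f_mle$tau_d, 1)
  short <- structure(list(dark_intervals = tt[1:4], n_intervals = 4L,
                          countable = TRUE), class = "dark_time_record")
  expect_error(fit_dark_time(short, "cdf_lsq"), "4")
})

test_that("the qPAINT index is the reciprocal dark time", {
  expect_equal(qpaint_index(1), 1)
  expect_equal(qpaint_index(1 / 0.0022), 0.0022)
  tau <- c(10, 20, 100)
  expect_true(all(diff(qpaint_index(tau)) < 0))
  expect_error(qpaint_index(0), "positive")
})

test_that("tau_d estimates ignore frame offsets and scale with exposure", {
  fr <- c(4, 5, 30, 31, 80, 140)
  a <- fit_dark_time(extract_dark_times(fr, 0.3), "mle_mean")
  b <- fit_dark_time(extract_dark_times(fr + 1000L, 0.3), "mle_mean")
  expect_equal(a$tau_d, b$tau_d)
  c2 <- fit_dark_time(extract_dark_times(fr, 0.6), "mle_mean")
  expect_equal(c2$tau_d, 2 * a$tau_d)
})

test_that("molecule counts are index ratios with sensible bookkeeping", {
  fits <- data.frame(cluster_id = 1:3, n_locs = c(40, 60, 5),
                     n_intervals = c(25, 30, 1),
                     xi = c(0.0044, 0.0022, NA),
                     tau_d = c(1 / 0.0044, 1 / 0.0022, NA),
                     countable = c(TRUE, TRUE, FALSE))
  cal <- structure(list(xi_unit = 0.0022, fit = NULL,
                        n_calibration_clusters = 50, threshold_nm = 55),
                   class = "qpaint_calibration")
  rep <- count_molecules(fits, cal)
  expect_equal(rep$per_cluster$n_molecules, c(2, 1))
  expect_equal(rep$per_cluster$n_rounded, c(2, 1))
  expect_equal(rep$n_uncountable, 1L)
  expect_equal(rep$mean_count, 1.5)
})

test_that("unit-index calibration recovers the single-site index from mixtures", {
  # clusters of 1, 2 and 3 sites at tau_dark = 454.5 s; the index histogram
  # peaks at multiples of 0.0022/s and the fitted first center is the unit
  fov <- c(150000, 150000)
  ks <- rep(c(1, 2, 3), times = c(120, 50, 30))
  xs <- c(); ys <- c(); sid <- c()
  set.seed(15)
  gx <- seq(2000, 148000, by = 2000)
  grid <- expand.grid(x = gx, y = gx)[seq_along(ks), ]
  for (i in seq_along(ks)) {
    k <- ks[i]
    xs <- c(xs, grid$x[i] + runif(k, -10, 10))
    ys <- c(ys, grid$y[i] + runif(k, -10, 10))
    sid <- c(sid, rep(i - 1L, k))
  }
  model <- emitter_model(xs, ys, structure_id = sid, fov = fov)
  kin <- kinetics_params()
  acq <- acq_config(n_frames = 18000, exposure = 0.3, fov = fov)
  sim <- simulate_paint(model, kin, acq, seed = 16)
  cs <- dbscan_cluster(sim$locs, eps = 20, min_pts = 10)
  fits <- cluster_dark_times(sim$locs, cs, acq$exposure)
  cal <- calibrate_unit_index(cs, fits, isolation_radius = 500)
  expect_lt(abs(cal$xi_unit - 0.0022) / 0.0022, 0.10)
  # empty calibration set errors
  far <- cs$clusters$max_pairwise_distance > 1e9
  expect_error(calibrate_unit_index(cs, fits, max_distance_threshold = 1e-9),
               "too few")
})

test_that("truncating the acquisition preserves the dark-time expectation", {
  fov <- c(100000, 100000)
  model <- make_vesicle_layout(0, 1, n_calibration_singles = 300, fov = fov, seed = 20)
  kin <- kinetics_params(imager_conc = 20e-9) # tau_dark 22.7 s
  acq <- acq_config(n_frames = 6000, exposure = 0.3, fov = fov)
  sim <- simulate_paint(model, kin, acq, seed = 21)
  xi_of <- function(locs) {
    v <- vapply(0:299, function(s) {
      fr <- locs$frame[locs$site_id == s]
      if (length(fr) < 2) return(NA_real_)
      r <- extract_dark_times(fr, 0.3)
      if (r$n_intervals < 2) return(NA_real_)
      fit_dark_time(r, "mle_mean")$tau_d
    }, numeric(1))
    v[is.finite(v)]
  }
  full <- xi_of(sim$locs)
  half <- xi_of(sim$locs[sim$locs$frame < 3000, ])
  se <- sqrt(var(full) / length(full) + var(half) / length(half))
  expect_lt(abs(mean(full) - mean(half)), 3 * se)
  expect_gt(var(half) / length(half), var(full) / length(full))
})
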