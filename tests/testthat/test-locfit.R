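test_that("blank frames produce an empty table, single spots are recovered", {
  blank <- matrix(rpois(400, 2), 20, 20)
  out <- fit_spots(blank, pixel_size = 108, detect_threshold = 500)
  expect_equal(nrow(out), 0)
  set.seed(21)
  mu <- spot_image(15, 7.3, 8.1, photons = 5000, bg = 0.01, sigma_px = 130 / 108)
  frame <- matrix(rpois(225, mu), 15, 15)
  fit <- fit_spots(frame, pixel_size = 108, psf_sigma_guess = 130,
                   detect_threshold = 500)
  expect_equal(nrow(fit), 1)
  expect_lt(abs(fit$x - 7.3 * 108), 3 * fit$sigma_loc_x)
  expect_lt(abs(fit$y - 8.1 * 108), 3 * fit$sigma_loc_y)
  expect_lt(abs(fit$photons - 5000) / 5000, 0.15)
})

test_that("fitted-position scatter matches the reported CRLB", {
  set.seed(22)
  mu <- spot_image(15, 7.3, 7.6, photons = 5000, bg = 2, sigma_px = 130 / 108)
  fits <- do.call(rbind, lapply(1:250, function(i) {
    frame <- matrix(rpois(225, mu), 15, 15)
    fit_spots(frame, pixel_size = 108, psf_sigma_guess = 130,
              detect_threshold = 500)
  }))
  expect_gt(nrow(fits), 240)
  expect_lt(abs(sd(fits$x) / mean(fits$sigma_loc_x) - 1), 0.15)
})

test_that("the CRLB shrinks monotonically along a photon ladder", {
  crlbs <- vapply(c(500, 2000, 8000, 32000), function(N) {
    set.seed(23)
    mu <- spot_image(15, 7.5, 7.5, photons = N, bg = 1, sigma_px = 130 / 108)
    f <- fit_spots(matrix(rpois(225, mu), 15, 15), pixel_size = 108,
                   detect_threshold = 100)
    f$sigma_loc_x[1]
  }, numeric(1))
  expect_true(all(diff(crlbs) < 0))
})

test_that("spots fit from simulated frames land on the emitting sites", {
  fov <- c(3240, 3240) # 30 x 30 pixels at 108 nm
  m <- emitter_model(c(700, 2400, 1500), c(800, 1900, 2700), fov = fov)
  kin <- kinetics_params(imager_conc = 500e-9) # busy blinking for a short stack
  acq <- acq_config(n_frames = 40, exposure = 0.3, fov = fov,
                    mean_photons = 5000, background_rate = 1, psf_sigma = 130)
  ev <- simulate_kinetics(m, kin, acq, seed = 31)
  frames <- simulate_frames(ev, m, acq, seed = 32)
  locs <- fit_spots(frames, pixel_size = 108, psf_sigma_guess = 130,
                    detect_threshold = 800)
  expect_gt(nrow(locs), 5)
  d <- vapply(seq_len(nrow(locs)), function(i)
    min(sqrt((locs$x[i] - m$x)^2 + (locs$y[i] - m$y)^2)), numeric(1))
  expect_lt(median(d), 15)
})

test_that("fiducial drift correction recovers a linear drift", {
  fov <- c(20000, 20000)
  set.seed(33)
  fid_x <- runif(5, 2000, 18000); fid_y <- runif(5, 2000, 18000)
  n_frames <- 2000
  # gold fiducials are bright: sub-nm per-frame localization precision
  tab <- sim_site_table(fid_x, fid_y, n_frames = n_frames, sigma = 0.5, seed = 33)
  dr <- make_linear_drift(n_frames, 50 / n_frames, -30 / n_frames)
  drifted <- apply_drift(tab, dr)
  fid <- data.frame(x = fid_x, y = fid_y, r = 200)
  out <- correct_drift(drifted, fid, smoothing_window = 100)
  expect_lt(abs(out$drift$dx[n_frames] - dr$dx[n_frames]), 2)
  expect_lt(abs(out$drift$dy[n_frames] - dr$dy[n_frames]), 2)
  # round trip: corrected positions match the undrifted table to within noise
  rms <- sqrt(mean((out$table$x - tab$x)^2 + (out$table$y - tab$y)^2))
  expect_lt(rms, 2 * 0.5)
  # idempotence: a second pass changes positions by less than 0.5 nm
  out2 <- correct_drift(out$table, fid, smoothing_window = 100)
  expect_lt(max(abs(out2$table$x - out$table$x)), 0.5)
  # null case: no drift estimates a near-zero trajectory
  out0 <- correct_drift(tab, fid, smoothing_window = 100)
  expect_lt(max(abs(out0$drift$dx)), 0.5)
  expect_error(correct_drift(tab, data.frame(x = 0, y = 0, r = 10)), "no fiducial")
})
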