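test_that("origami layouts have the designed pair geometry", {
  m <- make_origami_layout(3, "three_pair", fov = c(6000, 6000), seed = 4)
  expect_equal(nrow(m), 18)
  for (s in 0:2) {
    pts <- m[m$structure_id == s, c("x", "y")]
    pd <- function(i, j) sqrt(sum((pts[i, ] - pts[j, ])^2))
    # intra-pair separations {10, 17, 10} and overall extent 53
    expect_equal(c(pd(1, 2), pd(3, 4), pd(5, 6)), c(10, 17, 10),
                 tolerance = 1e-9)
    expect_equal(max(dist(pts)), 53, tolerance = 1e-9)
  }
  expect_equal(nrow(make_origami_layout(0, "three_pair", seed = 1)), 0)
  m1 <- make_origami_layout(1, "single_pair_6nm", fov = c(2000, 2000), seed = 2)
  # exhaustive O(n^2) pairwise distances: exactly one, 6.0 nm
  d <- as.vector(dist(m1[, c("x", "y")]))
  expect_length(d, 1)
  expect_equal(d, 6, tolerance = 1e-12)
})

test_that("origami placement fails cleanly when the field is too small", {
  expect_error(make_origami_layout(50, "three_pair", fov = c(300, 300), seed = 1),
               "placement")
})

test_that("npc rings hold 8 pairs spaced 12 nm with eightfold symmetry", {
  m <- make_npc_layout(1, ring_diameter = 107, pair_separation = 12,
                       fov = c(2000, 2000), seed = 9)
  expect_equal(nrow(m), 16)
  ctr <- colMeans(m[, c("x", "y")])
  # within-pair distances: nearest neighbor of every site is its partner
  D <- as.matrix(dist(m[, c("x", "y")])) + diag(1e9, 16)
  nn <- apply(D, 1, min)
  expect_equal(unname(nn), rep(12, 16), tolerance = 1e-9)
  # brute-force: the nearest neighbor index is the pair partner
  partner <- rep(seq(1, 15, by = 2), each = 2) + rep(c(1, 0), 8)
  expect_equal(unname(apply(D, 1, which.min)), partner)
  # rotating by 45 degrees about the center maps the site set onto itself
  th <- pi / 4
  rot <- cbind(c(cos(th), sin(th)), c(-sin(th), cos(th)))
  p <- sweep(as.matrix(m[, c("x", "y")]), 2, ctr) %*% t(rot)
  p <- sweep(p, 2, ctr, "+")
  D2 <- as.matrix(dist(rbind(p, as.matrix(m[, c("x", "y")]))))
  cross <- D2[1:16, 17:32]
  expect_lt(max(apply(cross, 1, min)), 1e-6)
  expect_error(make_npc_layout(1, ring_diameter = 10, pair_separation = 12),
               "ring_diameter")
})

test_that("vesicle layouts bound sites to the disc and isolate calibration sites", {
  m <- make_vesicle_layout(5, 46, diameter = 300, n_calibration_singles = 20,
                           fov = c(20000, 20000), seed = 3)
  ves <- m[m$structure_kind == "vesicle", ]
  singles <- m[m$role == "calibration_single", ]
  expect_equal(nrow(ves), 5 * 46)
  expect_equal(nrow(singles), 20)
  expect_equal(length(unique(m$structure_id)), 25)
  for (s in unique(ves$structure_id)) {
    p <- ves[ves$structure_id == s, ]
    # max-radius oracle: any two sites of one vesicle fit in the disc, so
    # the diameter is bounded by 300 nm and every site lies within one
    # radius of the disc center (within sampling shift of the centroid)
    expect_lte(max(dist(p[, c("x", "y")])), 300)
    cx <- mean(p$x); cy <- mean(p$y)
    expect_lt(max(sqrt((p$x - cx)^2 + (p$y - cy)^2)), 150 + 150 / sqrt(nrow(p)) * 4)
  }
  ctr <- aggregate(cbind(x, y) ~ structure_id, ves, mean)
  for (i in seq_len(nrow(singles))) {
    d <- sqrt((singles$x[i] - ctr$x)^2 + (singles$y[i] - ctr$y)^2)
    expect_gt(min(d), 3 * 300 - 150)
  }
  expect_equal(nrow(make_vesicle_layout(0, 46, n_calibration_singles = 0)), 0)
})

test_that("kinetics parameters derive the dark time from k_on and concentration", {
  k <- kinetics_params(tau_bright = 0.5, k_on = 2.2e6, imager_conc = 1e-9)
  expect_equal(k$tau_dark, 1 / 0.0022, tolerance = 1e-12)
  expect_error(kinetics_params(tau_bright = -1), "positive")
})

test_that("binding events are disjoint, sorted, inside the window, and seed-stable", {
  acq <- acq_config(n_frames = 400, exposure = 0.3, fov = c(3000, 3000))
  for (rep in 1:20) {
    kin <- kinetics_params(tau_bright = runif(1, 0.1, 2),
                           k_on = 2.2e6, imager_conc = runif(1, 5, 500) * 1e-9)
    m <- make_origami_layout(3, "three_pair", fov = c(3000, 3000), seed = rep)
    ev <- simulate_kinetics(m, kin, acq, seed = rep * 13)
    for (e in ev) {
      if (nrow(e) == 0) next
      expect_true(all(e[, 2] > e[, 1]))
      expect_true(all(e[, 1] >= 0) && all(e[, 2] <= acq$duration + 1e-9))
      if (nrow(e) > 1) expect_true(all(diff(e[, 1]) > 0) && all(e[-1, 1] >= e[-nrow(e), 2]))
    }
  }
  kin <- kinetics_params()
  m <- make_origami_layout(2, "three_pair", fov = c(3000, 3000), seed = 5)
  ev1 <- simulate_kinetics(m, kin, acq, seed = 77)
  ev2 <- simulate_kinetics(m, kin, acq, seed = 77)
  expect_identical(unclass(ev1), unclass(ev2))
})

test_that("a vanishing on-rate produces no binding events", {
  acq <- acq_config(n_frames = 100, exposure = 0.3, fov = c(1000, 1000))
  kin <- kinetics_params(k_on = 1e-12, imager_conc = 1e-12) # tau_dark >> 1e6 T
  m <- make_origami_layout(2, "single_pair_6nm", fov = c(1000, 1000), seed = 1)
  ev <- simulate_kinetics(m, kin, acq, seed = 3)
  expect_true(all(vapply(ev, nrow, 1L) == 0))
})

test_that("event counts match an independent renewal Monte-Carlo oracle", {
  fov <- c(120000, 120000)
  kin <- kinetics_params(imager_conc = 20e-9) # tau_dark 22.7 s
  acq <- acq_config(n_frames = 2000, exposure = 0.3, fov = fov)
  m <- make_vesicle_layout(0, 1, n_calibration_singles = 1000, fov = fov, seed = 2)
  ev <- simulate_kinetics(m, kin, acq, seed = 21)
  counts <- vapply(ev, nrow, 1L)
  oracle <- withr::with_seed(99, replicate(1000, mc_renewal_events(
    acq$duration, kin$tau_dark, kin$tau_bright)))
  se <- sqrt(var(counts) / 1000 + var(oracle) / 1000)
  expect_lt(abs(mean(counts) - mean(oracle)), 3 * se)
})

test_that("mean event gap approaches tau_dark when bright dwells vanish", {
  fov <- c(120000, 120000)
  kin <- kinetics_params(tau_bright = 1e-3 / 0.0022 * 1e-3, imager_conc = 100e-9)
  # tau_dark = 4.545 s, tau_bright ~ 5e-4 s
  acq <- acq_config(n_frames = 3000, exposure = 0.3, fov = fov)
  m <- make_vesicle_layout(0, 1, n_calibration_singles = 400, fov = fov, seed = 5)
  ev <- simulate_kinetics(m, kin, acq, seed = 8)
  gaps <- unlist(lapply(ev, function(e) if (nrow(e) > 1) diff(e[, 1])))
  se <- sd(gaps) / sqrt(length(gaps))
  expect_lt(abs(mean(gaps) - (kin$tau_dark + kin$tau_bright)), 3 * se)
})

test_that("localization emission respects photon statistics and detection", {
  fov <- c(5000, 5000)
  m <- make_origami_layout(4, "three_pair", fov = fov, seed = 6)
  kin <- kinetics_params(imager_conc = 50e-9)
  acq <- acq_config(n_frames = 500, exposure = 0.3, fov = fov,
                    mean_photons = 2000, detection_min_photons = 0)
  ev <- simulate_kinetics(m, kin, acq, seed = 31)
  locs <- emit_localizations(ev, m, acq, seed = 32)
  # one localization per bright (site, frame) overlap at zero threshold,
  # up to the rare zero-photon draw
  overlaps <- sum(vapply(ev, function(e) {
    if (nrow(e) == 0) return(0L)
    f0 <- pmax(0, floor(e[, 1] / acq$exposure))
    f1 <- pmin(acq$n_frames - 1, floor((e[, 2] - 1e-12) / acq$exposure))
    length(unique(unlist(mapply(seq.int, f0, f1, SIMPLIFY = FALSE))))
  }, 1L))
  expect_lte(nrow(locs), overlaps)
  expect_gt(nrow(locs) / overlaps, 0.98)
  # empty event list -> empty table
  e0 <- structure(rep(list(matrix(numeric(0), 0, 2)), nrow(m)),
                  duration = acq$duration, class = "binding_events")
  expect_equal(nrow(emit_localizations(e0, m, acq, seed = 1)), 0)
})

test_that("localization noise follows the photon-limited precision", {
  fov <- c(100000, 100000)
  m <- make_vesicle_layout(0, 1, n_calibration_singles = 500, fov = fov, seed = 7)
  kin <- kinetics_params(imager_conc = 100e-9)
  acq <- acq_config(n_frames = 200, exposure = 0.3, fov = fov,
                    mean_photons = 3000, detection_min_photons = 0,
                    psf_sigma = 130)
  ev <- simulate_kinetics(m, kin, acq, seed = 41)
  locs <- emit_localizations(ev, m, acq, seed = 42)
  expect_gt(nrow(locs), 1e4)
  err <- locs$x - m$x[locs$site_id + 1]
  # photons vary by frame overlap; normalize each error by its own sigma
  z <- err / locs$sigma_loc_x
  expect_lt(abs(sd(z) - 1), 0.05)
  # noise-free limit: enormous photon budgets localize to the true site
  # restrict to fully bright frames: partial-frame overlaps carry fewer
  # photons and correspondingly coarser precision even at huge budgets
  acq2 <- acq_config(n_frames = 50, exposure = 0.3, fov = fov,
                     mean_photons = 1e8, detection_min_photons = 9e7)
  ev2 <- simulate_kinetics(m[1:20, ], kin, acq2, seed = 43)
  locs2 <- emit_localizations(ev2, m[1:20, ], acq2, seed = 44)
  expect_gt(nrow(locs2), 0)
  expect_lt(max(abs(locs2$x - m$x[locs2$site_id + 1])), 0.1)
})

test_that("drift application shifts by exactly the per-frame displacement", {
  tab <- sim_site_table(c(100, 300), c(100, 200), n_frames = 50, sigma = 2)
  zero <- make_linear_drift(50, 0, 0)
  expect_equal(apply_drift(tab, zero), tab)
  dr <- make_linear_drift(50, 0.5, -0.2)
  shifted <- apply_drift(tab, dr)
  expect_equal(shifted$x - tab$x, 0.5 * tab$frame, tolerance = 1e-12)
  expect_equal(shifted$y - tab$y, -0.2 * tab$frame, tolerance = 1e-12)
  bad <- tab; bad$frame[1] <- 99L
  expect_error(apply_drift(bad, make_linear_drift(50, 1, 1)), "frame index")
})
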