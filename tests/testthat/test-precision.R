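test_that("precision summary averages the per-axis modes", {
  tab <- sim_site_table(c(0, 100), c(0, 0), n_frames = 30, sigma = 2)
  tab$sigma_loc_x <- 2; tab$sigma_loc_y <- 2
  expect_equal(summarize_precision(tab)$sigma_smlm, 2)
  one <- tab[1, ]; one$sigma_loc_x <- 3; one$sigma_loc_y <- 5
  expect_equal(summarize_precision(one)$sigma_smlm, 4)
  # bimodal sigma sample: the mode, not the mean
  set.seed(5)
  big <- sim_site_table(0, 0, n_frames = 1000, sigma = 1)
  s <- c(rnorm(800, 2, 0.1), rnorm(200, 8, 0.1))
  big$sigma_loc_x <- s; big$sigma_loc_y <- s
  ps <- summarize_precision(big)
  h <- hist(s, breaks = "FD", plot = FALSE)
  expect_equal(ps$sigma_x_mode, h$mids[which.max(h$counts)])
  expect_lt(abs(ps$sigma_smlm - 2), 0.3)
  expect_error(summarize_precision(big[0, ]), "empty")
})

test_that("precision summary ignores record order and translations", {
  set.seed(6)
  tab <- sim_site_table(c(0, 50), c(0, 20), n_frames = 200, sigma = 3)
  tab$sigma_loc_x <- abs(rnorm(nrow(tab), 3, 0.5))
  tab$sigma_loc_y <- abs(rnorm(nrow(tab), 4, 0.5))
  a <- summarize_precision(tab)
  perm <- tab[sample(nrow(tab)), ]
  moved <- tab; moved$x <- moved$x + 1e4; moved$y <- moved$y - 5e3
  expect_equal(summarize_precision(perm)$sigma_smlm, a$sigma_smlm)
  expect_equal(summarize_precision(moved)$sigma_smlm, a$sigma_smlm)
})

test_that("the 2.35-sigma resolution rule is linear", {
  expect_equal(resolution_estimate(0), 0)
  expect_equal(resolution_estimate(2), 4.7)
  expect_equal(resolution_estimate(10), 23.5)
  expect_equal(resolution_estimate(3 * 1.7), 3 * resolution_estimate(1.7))
  expect_error(resolution_estimate(-1), "non-negative")
})

test_that("NeNA recovers the localization precision of repeated sites", {
  set.seed(7)
  sx <- runif(40, 0, 4000); sy <- runif(40, 0, 4000)
  tab <- sim_site_table(sx, sy, n_frames = 120, sigma = 3, seed = 7)
  r <- nena(tab)
  expect_lt(abs(r$sigma_nena - 3) / 3, 0.15)
  expect_true(r$reliable)
  expect_gte(r$n_pairs, 100)
})

test_that("NeNA collapses to zero for noise-free repeats and flags uniform noise", {
  set.seed(8)
  sx <- runif(30, 0, 4000); sy <- runif(30, 0, 4000)
  tab0 <- sim_site_table(sx, sy, n_frames = 50, sigma = 0.0000001, seed = 8)
  r0 <- nena(tab0)
  expect_lt(r0$sigma_nena, 0.1)
  # spatially uniform unrelated points: mass goes to the background term
  set.seed(9)
  n <- 4000
  tabu <- data.frame(frame = sample(0:199, n, replace = TRUE),
                     x = runif(n, 0, 3000), y = runif(n, 0, 3000),
                     photons = 1000, sigma_loc_x = 3, sigma_loc_y = 3)
  ru <- nena(tabu)
  expect_false(ru$reliable)
  expect_error(nena(tabu[tabu$frame < 2, ][1:30, ]), "pairs")
})

test_that("NeNA is invariant to rigid motion of the table", {
  set.seed(11)
  sx <- runif(30, 0, 3000); sy <- runif(30, 0, 3000)
  tab <- sim_site_table(sx, sy, n_frames = 80, sigma = 2.5, seed = 11)
  r <- nena(tab)
  th <- 1.1
  rot <- tab
  rot$x <- cos(th) * tab$x - sin(th) * tab$y + 500
  rot$y <- sin(th) * tab$x + cos(th) * tab$y - 900
  expect_equal(nena(rot)$sigma_nena, r$sigma_nena, tolerance = 1e-6)
})
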