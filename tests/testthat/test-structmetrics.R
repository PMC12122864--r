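test_that("pair distance is exact for two point masses", {
  tab <- data.frame(x = rep(c(-6, 6), each = 50), y = 0)
  pd <- pair_distance(tab)
  expect_equal(pd$distance, 12)
  expect_equal(pd$sds, c(0, 0))
})

test_that("pair distance recovers simulated separations", {
  set.seed(41)
  mk <- function(sep, sigma, n) {
    th <- 0.6 # arbitrary pair orientation; principal axis must find it
    ux <- cos(th); uy <- sin(th)
    side <- rep(c(-sep / 2, sep / 2), each = n / 2)
    data.frame(x = side * ux + rnorm(n, 0, sigma),
               y = side * uy + rnorm(n, 0, sigma))
  }
  pd12 <- pair_distance(mk(12, 4, 500))
  expect_lt(abs(pd12$distance - 12), 1)
  pd6 <- pair_distance(mk(6, 1.4, 500))
  expect_lt(abs(pd6$distance - 6), 1)
  # rotation invariance under the principal-axis projection
  tab <- mk(10, 2, 400)
  th <- 1.3
  rot <- data.frame(x = cos(th) * tab$x - sin(th) * tab$y,
                    y = sin(th) * tab$x + cos(th) * tab$y)
  expect_equal(pair_distance(rot)$distance, pair_distance(tab)$distance,
               tolerance = 1e-6)
})

test_that("an unresolved pair raises a typed condition carrying the single-mode sd", {
  set.seed(42)
  tab <- data.frame(x = rnorm(300, 0, 5), y = rnorm(300, 0, 5))
  err <- tryCatch(pair_distance(tab), paintquant_unresolved = function(e) e)
  expect_s3_class(err, "paintquant_unresolved")
  expect_lt(abs(err$sigma_single - 5), 2)
  expect_error(pair_distance(tab[1:5, ]), "at least 20")
})

test_that("cross sections profile perpendicular structure and find wall pairs", {
  set.seed(43)
  # hollow tube seen in projection: two walls 35 nm apart along a segment
  n <- 2000
  along <- runif(n, 0, 1000)
  wall <- sample(c(-17.5, 17.5), n, replace = TRUE)
  th <- 0.35
  u <- c(cos(th), sin(th)); v <- c(-sin(th), cos(th))
  tab <- data.frame(x = 5000 + along * u[1] + (wall + rnorm(n, 0, 3)) * v[1],
                    y = 3000 + along * u[2] + (wall + rnorm(n, 0, 3)) * v[2],
                    frame = 0L, photons = 1000, sigma_loc_x = 3, sigma_loc_y = 3)
  p0 <- c(5000, 3000); p1 <- p0 + 1000 * u
  prof <- cross_section(tab, p0, p1, width = 120)
  expect_false(is.null(prof$pair))
  expect_lt(abs(prof$pair$peak_to_peak - 35), 3)
  # profile is invariant under rotating table and segment together
  phi <- 0.9
  R <- cbind(c(cos(phi), sin(phi)), c(-sin(phi), cos(phi)))
  tr <- as.matrix(tab[, c("x", "y")]) %*% t(R)
  tab2 <- tab; tab2$x <- tr[, 1]; tab2$y <- tr[, 2]
  prof2 <- cross_section(tab2, as.vector(R %*% p0), as.vector(R %*% p1), width = 120)
  expect_equal(prof2$counts, prof$counts)
  # points on the segment line itself: single peak, no pair reported
  online <- tab
  shift <- (wall + rnorm(n, 0, 3))
  online$x <- tab$x - shift * v[1]; online$y <- tab$y - shift * v[2]
  profl <- cross_section(online, p0, p1, width = 120)
  expect_null(profl$pair)
  empty <- cross_section(tab, c(0, 0), c(10, 0), width = 5)
  expect_equal(empty$n_locs, 0)
})

test_that("RESI averaging follows the inverse-variance closed form", {
  set.seed(44)
  # K = 100 equal-sigma localizations of one target: sigma/10 exactly
  tab <- data.frame(frame = 0:99, x = rnorm(100, 500, 3), y = rnorm(100, 500, 3),
                    photons = 1000, sigma_loc_x = 3, sigma_loc_y = 3)
  r <- resi_combine(list(tab), eps = 30, min_pts = 10)
  expect_equal(nrow(r), 1)
  expect_equal(r$sigma_resi, 3 / sqrt(100), tolerance = 1e-12)
  expect_equal(r$k, 100L)
  expect_equal(r$x, sum(tab$x / 9) / sum(rep(1 / 9, 100)), tolerance = 1e-12)
  # K = 1 returns the localization itself
  one <- tab[1, ]
  r1 <- resi_combine(list(one), eps = 30, min_pts = 1, group_min = 1)
  expect_equal(r1$x, one$x)
  expect_equal(r1$sigma_resi, 3)
  # sigma_resi never exceeds the best contributing precision, decreases in K
  ks <- c(4, 16, 64)
  s <- vapply(ks, function(k) {
    resi_combine(list(tab[seq_len(k), ]), eps = 30, min_pts = 2,
                 group_min = 2)$sigma_resi
  }, numeric(1))
  expect_true(all(diff(s) < 0))
  expect_equal(s, 3 / sqrt(ks), tolerance = 1e-12)
})

test_that("the weighted mean is the exact minimizer of the precision-weighted loss", {
  set.seed(45)
  xs <- rnorm(7, 100, 4); sig <- runif(7, 1, 5)
  w <- 1 / sig^2
  xhat <- sum(w * xs) / sum(w)
  grid <- seq(min(xs), max(xs), length.out = 20001)
  loss <- vapply(grid, function(p) sum(w * (p - xs)^2), numeric(1))
  expect_lt(abs(grid[which.min(loss)] - xhat), diff(grid[1:2]))
})

test_that("two close targets split across rounds become distinguishable", {
  set.seed(46)
  mk_round <- function(cx) {
    data.frame(frame = 0:49, x = rnorm(50, cx, 3), y = rnorm(50, 0, 3),
               photons = 1000, sigma_loc_x = 3, sigma_loc_y = 3)
  }
  r <- resi_combine(list(mk_round(-1), mk_round(1)), eps = 30, min_pts = 10)
  expect_equal(nrow(r), 2)
  sep <- abs(diff(sort(r$x)))
  expect_lt(abs(sep - 2), 3 * 2 * 3 / sqrt(50))
  expect_gt(sep, 3 * r$sigma_resi[1]) # resolved at the RESI precision
  expect_setequal(r$round_id, c(0, 1))
  expect_warning(resi_combine(list(mk_round(0), mk_round(0)[0, ]), eps = 30,
                              min_pts = 10), "empty")
})
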