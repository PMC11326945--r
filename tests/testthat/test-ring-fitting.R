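test_that("peak detection recovers an ideal ring from the true center", {
  img <- ideal_ring_image(radius = 10)
  peaks <- detect_peak_points(img, c(50, 50), fit_config(r_max_px = 20))
  expect_true(all(abs(peaks$radius_px[peaks$retained] - 10) <= 0.5))
  expect_gt(sum(peaks$retained), 300)
})

test_that("an offset seed spreads the per-ray peak radii by the offset", {
  img <- ideal_ring_image(radius = 10)
  peaks <- detect_peak_points(img, c(50, 52), fit_config(r_max_px = 20))
  r <- peaks$radius_px[peaks$retained]
  expect_lt(min(r), 8.6)
  expect_gt(max(r), 11.4)
  expect_true(all(r >= 7.5 & r <= 12.5))
})

test_that("peak radius matches a dense 1D oracle on a blurred ring", {
  # ring of radius 10 convolved with a sigma = 2 px Gaussian, noiseless;
  # oracle: brute-force maximisation of the analytic radial profile
  # I(r) = integral over the circle of the Gaussian, on a 0.01 px grid
  sigma <- 2; a <- 10
  size <- 101L; cen <- c(50, 50)
  g <- 0:(size - 1)
  # analytic ring x Gaussian: I(r) = a * exp(-(r-a)^2/2s^2) * I0s(ra/s^2),
  # with I0s the exponentially scaled Bessel function (numerically stable)
  ring_blur <- function(r)
    a * exp(-(r - a)^2 / (2 * sigma^2)) *
      besselI(r * a / sigma^2, 0, expon.scaled = TRUE)
  m <- matrix(0, size, size)
  for (k in seq_along(g)) {
    rr <- sqrt((g[k] - cen[1])^2 + (g - cen[2])^2)
    m[k, ] <- ring_blur(rr)
  }
  m <- m / max(m) * 100
  img <- image_plane(m, 20, "blurred", "sted")
  peaks <- detect_peak_points(img, cen, fit_config(r_max_px = 18))
  # per-ray oracle: maximise the same interpolated radial profile on a
  # 0.01 px grid and compare with the 0.25 px grid + parabolic refinement
  rgrid <- seq(5, 15, by = 0.01)
  for (i in seq(1, 360, by = 23)) {
    th <- peaks$angles[i]
    prof <- stedrings:::bilinear_sample(m, cen[1] + rgrid * cos(th),
                                        cen[2] + rgrid * sin(th))
    expect_lt(abs(peaks$radius_px[i] - rgrid[which.max(prof)]), 0.1)
  }
  # and the fitted circle should sit near the analytic profile maximum
  r_star <- rgrid[which.max(ring_blur(rgrid))]
  fit <- fit_circle_lsq(cbind(
    cen[1] + peaks$radius_px * cos(peaks$angles),
    cen[2] + peaks$radius_px * sin(peaks$angles)))
  expect_equal(fit$radius, r_star, tolerance = 0.1 / r_star)
})

test_that("outlier exclusion reproduces the hand-worked single-pass cases", {
  mk <- function(radii) {
    k <- length(radii)
    structure(list(center_used = c(0, 0),
                   angles = seq(0, 2 * pi, length.out = k + 1)[seq_len(k)],
                   radius_px = radii, intensity = rep(10, k),
                   retained = rep(TRUE, k)),
              class = "polar_peak_set")
  }
  # mean 10.3; 11.5 deviates 11.7% > 10% -> excluded
  out <- exclude_outlier_peaks(mk(c(10, 10, 10, 10, 11.5)), 0.10)
  expect_identical(out$retained, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  # mean 10.6; 13 (22.6%) and 9.5 (10.4%) go in the same single pass
  out2 <- exclude_outlier_peaks(mk(c(10.5, 9.5, 10, 10, 13)), 0.10)
  expect_identical(out2$retained, c(TRUE, FALSE, TRUE, TRUE, FALSE))
  # zero deviation keeps everything
  out3 <- exclude_outlier_peaks(mk(rep(7, 8)), 0.10)
  expect_true(all(out3$retained))
  # the rule is single-pass: re-applying to its own output only removes
  # points violating the rule at the newly recomputed mean
  out4 <- exclude_outlier_peaks(out2, 0.10)
  expect_identical(out4$retained, out2$retained)
})

test_that("Kasa circle fit is exact on true circles and rejects degeneracy", {
  th <- seq(0, 2 * pi, length.out = 37)[1:36]
  pts <- cbind(50 + 7 * cos(th), 50 + 7 * sin(th))
  fit <- fit_circle_lsq(pts)
  expect_equal(fit$center, c(50, 50), tolerance = 1e-9)
  expect_equal(fit$radius, 7, tolerance = 1e-9)
  # analytic circumcircle
  fit2 <- fit_circle_lsq(rbind(c(0, 0), c(2, 0), c(1, 1)))
  expect_equal(fit2$center, c(1, 0), tolerance = 1e-9)
  expect_equal(fit2$radius, 1, tolerance = 1e-9)
  expect_error(fit_circle_lsq(rbind(c(0, 0), c(1, 1), c(2, 2))),
               class = "degenerate_geometry_error")
  expect_error(fit_circle_lsq(rbind(c(0, 0), c(1, 1))),
               class = "degenerate_geometry_error")
})

test_that("segmentation fallback recovers spots, disks, and flags no signal", {
  spot <- gaussian_spot_image(sigma = 2)
  cfg <- fit_config(r_max_px = 10, fallback_threshold_mode = "fraction_of_max")
  fb <- segment_fallback(spot, c(30, 30), cfg)
  expect_equal(fb$method, "segmentation_fallback")
  expect_equal(fb$radius_px, 2.355, tolerance = 0.5 / 2.355)
  disk <- disk_image(radius = 5)
  fbd <- segment_fallback(disk, c(30, 30), cfg)
  expect_equal(fbd$center, c(30, 30), tolerance = 0.1)
  expect_equal(fbd$radius_px, 5, tolerance = 0.5 / 5)
  empty <- image_plane(matrix(0, 61, 61), 20, "empty", "sted")
  expect_error(segment_fallback(empty, c(30, 30), cfg),
               class = "no_signal_error")
})

test_that("fit_ring recovers rendered rings and branches on the dip test", {
  sc <- single_ring_scene(seed = 7, radius_nm = 160)  # r = 8 px
  fit <- fit_ring(sc$rendered$ch1,
                  c(sc$rendered$centers$row_px, sc$rendered$centers$col_px))
  expect_equal(fit$method, "radial_peak")
  expect_equal(fit$radius_px, sc$truth$rings$radius_px, tolerance = 0.25 / 8)
  # filled spot: no central dip -> segmentation fallback
  spot <- gaussian_spot_image(sigma = 2)
  fit2 <- fit_ring(spot, c(30, 30), fit_config(r_max_px = 10))
  expect_equal(fit2$method, "segmentation_fallback")
  # empty background -> typed no-signal error
  empty <- image_plane(matrix(0, 101, 101), 20, "bg", "sted")
  expect_error(fit_ring(empty, c(50, 50)), class = "no_signal_error")
})

test_that("circumference equals 2*pi*radius and is reported in nm", {
  sc <- single_ring_scene(seed = 11)
  fit <- fit_ring(sc$rendered$ch1,
                  c(sc$rendered$centers$row_px, sc$rendered$centers$col_px))
  expect_equal(fit$circumference_nm / fit$radius_nm, 2 * pi, tolerance = 1e-12)
  expect_equal(fit$radius_nm, fit$radius_px * 20, tolerance = 1e-12)
})

test_that("fit is equivariant under a 90-degree image rotation", {
  sc <- single_ring_scene(seed = 13)
  img <- sc$rendered$ch1
  seed <- c(sc$rendered$centers$row_px, sc$rendered$centers$col_px)
  fit <- fit_ring(img, seed)
  nr <- nrow(img$pixels)
  img_rot <- image_plane(rot90_matrix(img$pixels), img$pixel_size_nm,
                         "rot", "sted")
  fit_rot <- fit_ring(img_rot, c(seed[2], nr - 1 - seed[1]))
  expect_equal(fit_rot$radius_px, fit$radius_px, tolerance = 0.1 / fit$radius_px)
  expect_equal(fit_rot$center,
               c(fit$center[2], nr - 1 - fit$center[1]), tolerance = 0.1)
})

test_that("seeds too close to the image edge raise a bounds error", {
  img <- ideal_ring_image()
  expect_error(detect_peak_points(img, c(3, 50), fit_config(r_max_px = 20)),
               class = "bounds_error")
})
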