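test_that("identical configs give bit-identical truth and rasters", {
  cfg <- scene_config(n_cells = 2L, rng_seed = 99L)
  t1 <- generate_scene(cfg); t2 <- generate_scene(cfg)
  expect_identical(t1, t2)
  r1 <- render_scene(t1, noise = TRUE)
  r2 <- render_scene(t2, noise = TRUE)
  expect_identical(r1$ch1$pixels, r2$ch1$pixels)
  expect_identical(r1$ch2$pixels, r2$ch2$pixels)
  expect_identical(r1$centers, r2$centers)
})

test_that("full coupling makes the channel-2 truth proportional to channel 1", {
  cfg <- scene_config(n_cells = 3L, coupling_alpha = 1, rng_seed = 5L)
  tr <- generate_scene(cfg)
  for (i in seq_len(nrow(tr$rings))) {
    r <- cor(tr$angular_truth_ch1[, i], tr$angular_truth_ch2[, i])
    expect_equal(r, 1.0, tolerance = 1e-12)
  }
})

test_that("zero coupling gives uncorrelated angular truths on average", {
  ## Monte-Carlo over independent patch draws: >= 200 rings, fixed seeds
  rs <- numeric(0)
  for (s in 1:13) {
    cfg <- scene_config(image_size_px = c(400L, 400L), n_cells = 16L,
                        rings_per_cell_range = c(1L, 1L),
                        cluster_probability = 0, coupling_alpha = 0,
                        rng_seed = 1000L + s)
    tr <- generate_scene(cfg)
    rs <- c(rs, vapply(seq_len(nrow(tr$rings)), function(i)
      cor(tr$angular_truth_ch1[, i], tr$angular_truth_ch2[, i]), 1))
  }
  expect_gte(length(rs), 200)
  expect_lt(abs(mean(rs)), 0.05)
})

test_that("planted labels partition every ring and match circle geometry", {
  cfg <- scene_config(n_cells = 3L, rings_per_cell_range = c(2L, 2L),
                      cluster_probability = 1, rng_seed = 21L)
  tr <- generate_scene(cfg)
  expect_equal(nrow(tr$expected_labels), length(tr$angles))
  ## Between + Outside = K for every ring by construction of a logical
  k <- length(tr$angles)
  cnt <- colSums(tr$expected_labels) + colSums(!tr$expected_labels)
  expect_true(all(cnt == k))
  ## isolated ring: all Outside
  iso <- single_ring_scene(seed = 3)$truth
  expect_false(any(iso$expected_labels))
  ## infinite gap: everything Between on a multi-ring scene
  expect_true(all(expected_labels(tr, gap_nm = 1e9)))
  expect_error(expected_labels(tr, gap_nm = -1), class = "validation_error")
})

test_that("tangent rings at the analytic geometry give the expected Between arc", {
  ## two r = 10 px rings, centers 20 px apart, 20 nm px, 30 nm gap:
  ## Between iff cos(theta) >= 0.919375, i.e. 47 of 360 one-degree samples
  rings <- data.frame(cell_id = c(1L, 1L), center_row = c(50, 70),
                      center_col = c(50, 50), radius_px = c(10, 10),
                      ring_id = 1:2, radius_nm = c(200, 200))
  truth <- structure(list(
    rings = rings, angles = seq(0, 2 * pi, length.out = 361)[1:360],
    params = list(pixel_size_nm = 20)), class = "scene_ground_truth")
  labs <- expected_labels(truth, gap_nm = 30)
  expect_equal(sum(labs[, 1]), 47)
  expect_equal(sum(labs[, 2]), 47)
  expect_equal(mean(labs[, 1]), 0.129, tolerance = 1 / 360 / 0.129)
})

test_that("rendering geometry, linearity and the Gaussian FWHM check hold", {
  ## uniform ring, noise off: crest on the circle within half a pixel
  sc <- single_ring_scene(seed = 31, radius_nm = 200, patch_count_range = c(0L, 0L),
                          background_level = 0)
  px <- sc$rendered$ch1$pixels
  crest <- which(px == max(px), arr.ind = TRUE)[1, ] - 1
  d <- sqrt(sum((crest - c(sc$truth$rings$center_row,
                           sc$truth$rings$center_col))^2))
  expect_lt(abs(d - sc$truth$rings$radius_px), 0.5 + 0.5)  # crest on pixel grid
  ## doubling the photon budget doubles every foreground pixel (noise off)
  sc2 <- single_ring_scene(seed = 31, radius_nm = 200,
                           patch_count_range = c(0L, 0L),
                           background_level = 0, photon_budget = 200)
  expect_equal(sc2$rendered$ch1$pixels, 2 * px, tolerance = 1e-10)
  ## total noiseless intensity is linear in photon_budget
  expect_equal(sum(sc2$rendered$ch1$pixels), 2 * sum(px), tolerance = 1e-10)
  ## a rendered Gaussian spot thresholded at half maximum has diameter
  ## 2.355 * sigma within a pixel
  sigma <- 3
  spot <- gaussian_spot_image(size = 61L, sigma = sigma)$pixels
  seg <- spot >= max(spot) / 2
  diam <- max(rowSums(seg), colSums(seg))
  expect_equal(diam, 2.355 * sigma, tolerance = 1 / (2.355 * sigma))
})

test_that("invalid configurations and impossible placements raise typed errors", {
  expect_error(scene_config(radius_range_nm = c(300, 80)),
               class = "validation_error")
  expect_error(scene_config(radius_range_nm = c(30, 300)),
               class = "validation_error")  # below 2 px
  expect_error(scene_config(psf_fwhm_sted_nm = 250, psf_fwhm_conf_nm = 60),
               class = "validation_error")
  expect_error(scene_config(coupling_alpha = 1.5), class = "validation_error")
  ## too many rings for the canvas -> bounded retries then explicit failure
  cfg <- scene_config(image_size_px = c(150L, 150L), n_cells = 40L,
                      rings_per_cell_range = c(3L, 3L),
                      radius_range_nm = c(250, 300), cluster_probability = 0,
                      rng_seed = 2L)
  expect_error(generate_scene(cfg), class = "placement_failure_error")
})

test_that("outside enrichment multiplies the companion truth on Outside arcs", {
  cfg <- scene_config(n_cells = 1L, rings_per_cell_range = c(2L, 2L),
                      cluster_probability = 1, coupling_alpha = 0.5,
                      outside_enrichment_beta = 3, rng_seed = 8L)
  tr <- generate_scene(cfg)
  cfg0 <- cfg; cfg0$outside_enrichment_beta <- 1
  tr0 <- generate_scene(cfg0)
  lab <- tr$expected_labels
  expect_equal(tr$angular_truth_ch2[lab], tr0$angular_truth_ch2[lab])
  expect_equal(tr$angular_truth_ch2[!lab], 3 * tr0$angular_truth_ch2[!lab])
})
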