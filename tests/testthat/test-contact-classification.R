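deg_angles <- seq(0, 2 * pi, length.out = 361)[1:360]

test_that("arc labeling reproduces the tangent-ring analytic geometry", {
  a <- circle_fit_stub(c(50, 50), 10, 20, id = 1)
  b <- circle_fit_stub(c(70, 50), 10, 20, id = 2)
  ## single ring: everything Outside
  lab1 <- label_arc_samples(a, list(a), deg_angles)
  expect_false(any(lab1$is_between))
  ## 30 nm gap at 20 nm pixels: Between iff cos(theta) >= 0.919375
  lab <- label_arc_samples(a, list(a, b), deg_angles)
  expect_equal(sum(lab$is_between), 47)
  expect_equal(mean(lab$is_between), 0.129, tolerance = (1 / 360) / 0.129)
  ## huge gap: everything Between on a two-ring image
  lab_inf <- label_arc_samples(a, list(a, b), deg_angles,
                               contact_config(gap_nm = 1e9))
  expect_true(all(lab_inf$is_between))
  expect_error(label_arc_samples(a, list(), deg_angles),
               class = "validation_error")
  expect_error(contact_config(gap_nm = 0), class = "validation_error")
})

test_that("widening the gap never removes Between samples", {
  set.seed(29)
  a <- circle_fit_stub(c(50, 50), 10, 20, id = 1)
  b <- circle_fit_stub(c(50 + runif(1, 18, 25), 50), runif(1, 5, 10), 20, 2)
  prev <- 0L
  for (gap in c(10, 30, 60, 120, 240)) {
    n <- sum(label_arc_samples(a, list(a, b), deg_angles,
                               contact_config(gap_nm = gap))$is_between)
    expect_gte(n, prev)
    prev <- n
  }
})

test_that("between/outside means partition the profile and handle empties", {
  prof <- list(intensities_ch2 = c(4, 4, 2, 2), angles = deg_angles[1:4])
  lab <- list(is_between = c(TRUE, TRUE, FALSE, FALSE))
  bo <- between_outside_means(prof, lab)
  expect_equal(unlist(bo), c(mean_between = 4, mean_outside = 2,
                             n_between = 2, n_outside = 2))
  ## all-Outside: Between mean undefined
  bo2 <- between_outside_means(prof, list(is_between = rep(FALSE, 4)))
  expect_true(is.na(bo2$mean_between))
  expect_equal(bo2$n_between, 0)
  expect_equal(bo2$n_between + bo2$n_outside, 4)
  expect_error(
    between_outside_means(prof, list(is_between = rep(FALSE, 5))),
    class = "validation_error")
})

test_that("cell classification follows the pooled ratio with a conservative tie", {
  rec <- function(mb, mo, nb = 100, no = 260)
    data.frame(cell_id = 1, mean_between_ch2 = mb, mean_outside_ch2 = mo,
               n_between = nb, n_outside = no)
  one <- classify_cell(rec(3, 5))
  expect_equal(one$predominant, "outside")
  expect_equal(one$ratio_outside_over_between, 5 / 3)
  expect_equal(classify_cell(rec(5, 3))$predominant, "between")
  expect_equal(classify_cell(rec(4, 4))$predominant, "between")  # tie rule
  ## isolated-ring cell: no Between samples -> indeterminate
  iso <- classify_cell(rec(NA, 5, nb = 0, no = 360))
  expect_equal(iso$predominant, "indeterminate")
  expect_true(is.na(iso$ratio_outside_over_between))
  ## pooling across rings is count-weighted
  two <- classify_cell(rbind(rec(2, 1, nb = 300, no = 60),
                             rec(10, 2, nb = 10, no = 300)))
  pooled_b <- (2 * 300 + 10 * 10) / 310
  pooled_o <- (1 * 60 + 2 * 300) / 360
  expect_equal(two$ratio_outside_over_between, pooled_o / pooled_b)
  expect_error(classify_cell(rec(1, 1)[0, ]), class = "validation_error")
})

test_that("outside percentage excludes indeterminate cells with a tally", {
  cells <- data.frame(predominant = c(rep("outside", 3), rep("between", 7),
                                      rep("indeterminate", 2)))
  op <- outside_percentage(cells)
  expect_equal(op$percentage, 30.0)
  expect_equal(op$n_indeterminate, 2)
  all_ind <- data.frame(predominant = rep("indeterminate", 4))
  expect_message(op2 <- outside_percentage(all_ind), "indeterminate")
  expect_true(is.na(op2$percentage))
})

test_that("fitted-circle labels agree with the planted truth on noiseless scenes", {
  agree <- c(); n_lab <- 0
  for (s in c(71, 72, 73)) {
    cfg <- scene_config(n_cells = 2L, rings_per_cell_range = c(2L, 2L),
                        cluster_probability = 1, rng_seed = s)
    tr <- generate_scene(cfg)
    rd <- render_scene(tr, noise = FALSE)
    res <- analyze_image(rd$ch1, rd$ch2, rd$centers)
    for (i in seq_len(nrow(tr$rings))) {
      expect_equal(res$records$n_between[i] + res$records$n_outside[i], 360)
      agree <- c(agree, mean(res$labelings[[i]]$is_between ==
                               tr$expected_labels[, i]))
    }
  }
  expect_gte(mean(agree), 0.99)
})

test_that("planted outside enrichment raises the measured ratio monotonically", {
  ## At a tangency both membranes coincide, so Between samples carry the
  ## signal of two membranes, and the companion channel's wide PSF smears
  ## bright Outside arcs into the narrow contact arc. The measured
  ## outside/between ratio is therefore biased below the planted beta;
  ## what must hold is that the ratio increases monotonically in beta and
  ## separates enriched from contact-enriched cells.
  ratio_for <- function(beta, s) {
    cfg <- scene_config(image_size_px = c(170L, 170L), n_cells = 1L,
                        rings_per_cell_range = c(2L, 2L),
                        cluster_probability = 1, coupling_alpha = 0,
                        patch_count_range = c(0L, 0L),
                        outside_enrichment_beta = beta, background_level = 0,
                        rng_seed = s)
    rd <- render_scene(generate_scene(cfg), noise = FALSE)
    res <- analyze_image(rd$ch1, rd$ch2, rd$centers)
    classify_cell(res$records[res$records$failure == "", ])$
      ratio_outside_over_between
  }
  seeds <- c(77L, 78L, 79L)
  r_low <- vapply(seeds, function(s) ratio_for(1 / 3, s), 1)
  r_one <- vapply(seeds, function(s) ratio_for(1, s), 1)
  r_high <- vapply(seeds, function(s) ratio_for(3, s), 1)
  expect_true(all(r_low < r_one & r_one < r_high))
  ## the two planted directions remain cleanly separable
  expect_gt(min(r_high), max(r_low))
})
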