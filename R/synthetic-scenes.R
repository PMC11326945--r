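## Seeded synthetic two-channel nanoscopy scenes with exported ground truth.
## These emulate the statistical structure the ring pipeline assumes:
## ring-shaped membrane labels with patchy angular emission, a companion
## channel coupled to the membrane channel's angular truth, tangent ring
## clusters, Gaussian PSF blur at two scales, constant background and
## Poisson shot noise.

#' Synthetic-scene configuration
#'
#' Defaults describe a plausible STED/confocal acquisition of yeast
#' peroxisomes: 20 nm pixels, 60 nm STED and 250 nm confocal FWHM, ring
#' radii of 80-300 nm, and a peak photon budget of 100 counts (peak
#' signal-to-noise around 10).
#'
#' @param image_size_px integer pair (rows, cols).
#' @param pixel_size_nm physical pixel size.
#' @param n_cells number of cells in the scene.
#' @param rings_per_cell_range integer pair, rings drawn per cell.
#' @param radius_range_nm true ring radius range, nm.
#' @param cluster_probability probability that a cell's next ring is placed
#'   tangent to one of its previous rings (a peroxisome cluster).
#' @param patch_count_range integer pair, membrane patches per ring.
#' @param patch_concentration von Mises concentration (kappa) of each patch.
#' @param patch_amplitude patch height as a ratio over the baseline.
#' @param coupling_alpha weight in `[0, 1]` of the membrane channel's
#'   normalized angular truth in the companion channel's truth (0 =
#'   independent patches, 1 = proportional).
#' @param outside_enrichment_beta multiplier applied to the companion
#'   channel's truth over Outside arcs (1 = no enrichment; > 1 plants a
#'   cytosol-exposed enrichment, < 1 a contact enrichment).
#' @param contact_gap_nm boundary gap used to decide the planted
#'   Between/Outside labels.
#' @param psf_fwhm_sted_nm,psf_fwhm_conf_nm Gaussian PSF FWHM per channel.
#' @param background_level constant background, photons per pixel.
#' @param photon_budget expected peak (crest) photon count of a unit-truth
#'   membrane after blur.
#' @param n_truth_angles number K of angles at which angular truths and
#'   labels are tabulated.
#' @param rng_seed integer seed; identical configs give identical scenes.
#'
#' @return A list of class `scene_config`.
#' @export
scene_config <- function(image_size_px = c(300L, 300L), pixel_size_nm = 20,
                         n_cells = 4L, rings_per_cell_range = c(1L, 3L),
                         radius_range_nm = c(80, 300),
                         cluster_probability = 0.5,
                         patch_count_range = c(2L, 5L),
                         patch_concentration = 4, patch_amplitude = 2,
                         coupling_alpha = 0.5, outside_enrichment_beta = 1,
                         contact_gap_nm = 30,
                         psf_fwhm_sted_nm = 60, psf_fwhm_conf_nm = 250,
                         background_level = 2, photon_budget = 100,
                         n_truth_angles = 360L, rng_seed = 1L) {
  cfg <- list(image_size_px = as.integer(image_size_px),
              pixel_size_nm = pixel_size_nm, n_cells = as.integer(n_cells),
              rings_per_cell_range = as.integer(rings_per_cell_range),
              radius_range_nm = radius_range_nm,
              cluster_probability = cluster_probability,
              patch_count_range = as.integer(patch_count_range),
              patch_concentration = patch_concentration,
              patch_amplitude = patch_amplitude,
              coupling_alpha = coupling_alpha,
              outside_enrichment_beta = outside_enrichment_beta,
              contact_gap_nm = contact_gap_nm,
              psf_fwhm_sted_nm = psf_fwhm_sted_nm,
              psf_fwhm_conf_nm = psf_fwhm_conf_nm,
              background_level = background_level,
              photon_budget = photon_budget,
              n_truth_angles = as.integer(n_truth_angles),
              rng_seed = as.integer(rng_seed))
  validate_scene_config(cfg)
  structure(cfg, class = "scene_config")
}

validate_scene_config <- function(cfg) {
  ordered <- function(x) length(x) == 2L && x[1] <= x[2]
  if (!ordered(cfg$rings_per_cell_range) || !ordered(cfg$radius_range_nm) ||
      !ordered(cfg$patch_count_range))
    stop_typed("validation_error", "range parameters must satisfy min <= max")
  if (cfg$radius_range_nm[1] < 2 * cfg$pixel_size_nm)
    stop_typed("validation_error",
               "minimum radius must be at least 2 pixels (%g nm)",
               2 * cfg$pixel_size_nm)
  if (cfg$psf_fwhm_conf_nm <= cfg$psf_fwhm_sted_nm)
    stop_typed("validation_error",
               "confocal FWHM must exceed the STED FWHM")
  if (cfg$coupling_alpha < 0 || cfg$coupling_alpha > 1)
    stop_typed("validation_error", "coupling_alpha must lie in [0, 1]")
  if (cfg$cluster_probability < 0 || cfg$cluster_probability > 1)
    stop_typed("validation_error", "cluster_probability must lie in [0, 1]")
  if (cfg$outside_enrichment_beta <= 0 || cfg$photon_budget <= 0)
    stop_typed("validation_error", "beta and photon_budget must be positive")
  invisible(TRUE)
}

## Evaluate code with a temporary RNG state so scene generation never
## perturbs (nor depends on) the caller's stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## Uniform integer draw from [lo, hi]; length-1 safe (avoids sample(n, 1)).
sample_range <- function(lo, hi) if (lo >= hi) lo else sample(lo:hi, 1L)

## Patch mixture on K angles: baseline 1 plus von Mises bumps normalized
## to unit peak, scaled by the patch amplitude.
patch_mixture <- function(angles, n_patches, kappa, amplitude) {
  f <- rep(1, length(angles))
  if (n_patches > 0L) {
    mus <- stats::runif(n_patches, 0, 2 * pi)
    for (mu in mus)
      f <- f + amplitude * exp(kappa * (cos(angles - mu) - 1))
  }
  f
}

psf_sigma_px <- function(fwhm_nm, pixel_size_nm) {
  fwhm_nm / (2 * sqrt(2 * log(2))) / pixel_size_nm
}

#' Generate a ground-truthed synthetic scene
#'
#' Places rings (optionally tangent within a cell, emulating peroxisome
#' clusters), draws each ring's angular emission truth for both channels,
#' and tabulates the planted Between/Outside labels from the true
#' geometry. The companion channel's truth is
#' `alpha * normalized ch1 truth + (1 - alpha) * independent patches`,
#' multiplied by `outside_enrichment_beta` over Outside arcs. Identical
#' configs (including seed) give identical output.
#'
#' @param config a [scene_config()].
#' @return A `scene_ground_truth`: ring table (`cell_id`, true center px,
#'   true radius), angular truths (`K x n_rings` matrices), planted labels,
#'   and the config used.
#' @export
generate_scene <- function(config) {
  validate_scene_config(config)
  with_seed(config$rng_seed, {
    px <- config$pixel_size_nm
    r_rng_px <- config$radius_range_nm / px
    sig_conf <- psf_sigma_px(config$psf_fwhm_conf_nm, px)
    margin <- r_rng_px[2] + ceiling(3 * sig_conf) + 3
    nr <- config$image_size_px[1]; nc <- config$image_size_px[2]
    if (nr - 2 * margin < 1 || nc - 2 * margin < 1)
      stop_typed("validation_error",
                 "image too small for the radius range and PSF margins")
    clear_px <- 2 * config$contact_gap_nm / px  # unambiguous Outside gap

    rings <- data.frame(cell_id = integer(), center_row = numeric(),
                        center_col = numeric(), radius_px = numeric())
    for (cell in seq_len(config$n_cells)) {
      n_rings <- sample_range(config$rings_per_cell_range[1],
                              config$rings_per_cell_range[2])
      first_of_cell <- nrow(rings) + 1L
      for (k in seq_len(n_rings)) {
        r_new <- stats::runif(1, r_rng_px[1], r_rng_px[2])
        placed <- FALSE
        cluster <- k > 1L && stats::runif(1) < config$cluster_probability
        for (try in seq_len(500L)) {
          if (cluster) {
            cand <- first_of_cell:nrow(rings)   # length-1 safe: no sample(n, 1)
            base <- rings[if (length(cand) == 1L) cand else sample(cand, 1L), ]
            ang <- stats::runif(1, 0, 2 * pi)
            cen <- c(base$center_row, base$center_col) +
              (base$radius_px + r_new) * c(cos(ang), sin(ang))
          } else {
            cen <- c(stats::runif(1, margin, nr - 1 - margin),
                     stats::runif(1, margin, nc - 1 - margin))
          }
          if (any(cen < margin) || cen[1] > nr - 1 - margin ||
              cen[2] > nc - 1 - margin) next
          ok <- TRUE
          if (nrow(rings)) {
            d <- sqrt((rings$center_row - cen[1])^2 +
                      (rings$center_col - cen[2])^2)
            gap <- d - rings$radius_px - r_new
            tangent_to <- if (cluster)
              which(abs(rings$center_row - cen[1]) < 1e-9 &
                    abs(rings$center_col - cen[2]) < 1e-9) else integer(0)
            if (cluster) {
              ## the chosen base ring is exactly tangent; all others must
              ## either be tangent cluster members or keep clear distance
              ok <- all(gap > -1 & (gap > clear_px | abs(gap) <= 1))
            } else {
              ok <- all(gap > clear_px)
            }
          }
          if (ok) { placed <- TRUE; break }
        }
        if (!placed)
          stop_typed("placement_failure_error",
                     "could not place ring %d of cell %d after 500 tries",
                     k, cell)
        rings <- rbind(rings, data.frame(cell_id = cell, center_row = cen[1],
                                         center_col = cen[2],
                                         radius_px = r_new))
      }
    }
    rings$ring_id <- seq_len(nrow(rings))
    rings$radius_nm <- rings$radius_px * px

    K <- config$n_truth_angles
    angles <- angle_grid(K)
    n <- nrow(rings)
    truth1 <- matrix(0, K, n); truth2 <- matrix(0, K, n)
    for (i in seq_len(n)) {
      np1 <- sample_range(config$patch_count_range[1], config$patch_count_range[2])
      np2 <- sample_range(config$patch_count_range[1], config$patch_count_range[2])
      f1 <- patch_mixture(angles, np1, config$patch_concentration,
                          config$patch_amplitude)
      g <- patch_mixture(angles, np2, config$patch_concentration,
                         config$patch_amplitude)
      truth1[, i] <- f1
      truth2[, i] <- config$coupling_alpha * f1 / mean(f1) +
        (1 - config$coupling_alpha) * g / mean(g)
    }

    truth <- structure(list(rings = rings, angles = angles,
                            angular_truth_ch1 = truth1,
                            angular_truth_ch2 = truth2,
                            expected_labels = NULL, params = config),
                       class = "scene_ground_truth")
    labs <- expected_labels(truth, config$contact_gap_nm)
    truth$expected_labels <- labs
    if (config$outside_enrichment_beta != 1)
      truth$angular_truth_ch2 <- truth$angular_truth_ch2 *
        ifelse(labs, 1, config$outside_enrichment_beta)
    truth
  })
}

#' @export
print.scene_ground_truth <- function(x, ...) {
  cat(sprintf("<scene_ground_truth> %d rings in %d cells, %d x %d px, seed %d\n",
              nrow(x$rings), x$params$n_cells, x$params$image_size_px[1],
              x$params$image_size_px[2], x$params$rng_seed))
  invisible(x)
}

#' Planted Between/Outside labels from the true geometry
#'
#' An angle on ring `i` is Between when the boundary-to-boundary distance
#' from its membrane point to any other true ring is at most `gap_nm`;
#' Outside otherwise. Serves as the oracle for [label_arc_samples()] run on
#' fitted circles.
#'
#' @param truth a `scene_ground_truth`.
#' @param gap_nm positive contact gap, nm.
#' @return Logical `K x n_rings` matrix, TRUE = Between.
#' @export
expected_labels <- function(truth, gap_nm) {
  if (!is.numeric(gap_nm) || length(gap_nm) != 1L || gap_nm <= 0)
    stop_typed("validation_error", "gap_nm must be a single positive number")
  rings <- truth$rings
  px <- truth$params$pixel_size_nm
  K <- length(truth$angles)
  out <- matrix(FALSE, K, nrow(rings))
  for (i in seq_len(nrow(rings))) {
    p_row <- rings$center_row[i] + rings$radius_px[i] * cos(truth$angles)
    p_col <- rings$center_col[i] + rings$radius_px[i] * sin(truth$angles)
    for (j in seq_len(nrow(rings))) {
      if (j == i) next
      d <- sqrt((p_row - rings$center_row[j])^2 +
                (p_col - rings$center_col[j])^2)
      out[, i] <- out[, i] | (abs(d - rings$radius_px[j]) * px <= gap_nm)
    }
  }
  out
}

## Linear periodic interpolation of an angular truth at arbitrary angles.
interp_angular <- function(angles_tab, values, at) {
  K <- length(angles_tab)
  step <- 2 * pi / K
  pos <- (at %% (2 * pi)) / step
  i0 <- floor(pos); fr <- pos - i0
  v0 <- values[(i0 %% K) + 1L]
  v1 <- values[((i0 + 1L) %% K) + 1L]
  v0 * (1 - fr) + v1 * fr
}

#' Render a scene into two image planes plus a centers table
#'
#' Each ring's angular truth is deposited along its true circle at a fine
#' arc step, convolved with the channel's isotropic Gaussian PSF, scaled so
#' a unit-truth membrane crest carries `photon_budget` expected photons,
#' offset by the constant background, and (optionally) degraded with
#' Poisson noise. The centers table carries the true centers jittered by at
#' most 2 px, emulating manual center clicking.
#'
#' @param truth a `scene_ground_truth` from [generate_scene()].
#' @param noise logical; apply Poisson shot noise (seeded from the scene
#'   config). With `noise = FALSE` rendering is fully deterministic given
#'   the truth.
#' @param image_id identifier written into the centers table.
#'
#' @return List with `ch1`, `ch2` ([image_plane()]s) and `centers`
#'   (data.frame `image_id, cell_id, ring_id, row_px, col_px`).
#' @export
render_scene <- function(truth, noise = TRUE, image_id = "scene") {
  cfg <- truth$params
  nr <- cfg$image_size_px[1]; nc <- cfg$image_size_px[2]
  sig1 <- psf_sigma_px(cfg$psf_fwhm_sted_nm, cfg$pixel_size_nm)
  sig2 <- psf_sigma_px(cfg$psf_fwhm_conf_nm, cfg$pixel_size_nm)
  rings <- truth$rings

  for (i in seq_len(nrow(rings))) {
    ext <- rings$radius_px[i] + 3 * sig2
    if (rings$center_row[i] - ext < 0 || rings$center_row[i] + ext > nr - 1 ||
        rings$center_col[i] - ext < 0 || rings$center_col[i] + ext > nc - 1)
      stop_typed("bounds_error", "ring %d extends beyond the image bounds",
                 rings$ring_id[i])
  }

  deposit <- function(truth_mat, sigma) {
    canvas <- matrix(0, nr, nc)
    ## crest calibration: a blurred unit line of linear density lambda has
    ## peak lambda / (sigma * sqrt(2*pi)); choose lambda so the crest of a
    ## unit-truth membrane equals photon_budget
    lambda <- cfg$photon_budget * sigma * sqrt(2 * pi)
    for (i in seq_len(nrow(rings))) {
      r <- rings$radius_px[i]
      n_dep <- max(length(truth$angles), ceiling(2 * pi * r / 0.2))
      th <- seq(0, 2 * pi, length.out = n_dep + 1L)[seq_len(n_dep)]
      ds <- 2 * pi * r / n_dep
      val <- interp_angular(truth$angles, truth_mat[, i], th) * ds * lambda
      rr <- rings$center_row[i] + r * cos(th)
      cc <- rings$center_col[i] + r * sin(th)
      i0 <- floor(rr); j0 <- floor(cc)
      fr <- rr - i0; fc <- cc - j0
      ## bilinear splat onto the four neighbouring pixels (vectorized;
      ## duplicate targets are aggregated before the in-place add)
      lin <- c((j0) * nr + i0 + 1L, (j0) * nr + i0 + 2L,
               (j0 + 1L) * nr + i0 + 1L, (j0 + 1L) * nr + i0 + 2L)
      w <- c(val * (1 - fr) * (1 - fc), val * fr * (1 - fc),
             val * (1 - fr) * fc, val * fr * fc)
      agg <- rowsum(w, lin)
      tgt <- as.integer(rownames(agg))
      canvas[tgt] <- canvas[tgt] + agg[, 1]
    }
    canvas
  }

  blur <- function(canvas, sigma) {
    img <- EBImage::gblur(EBImage::Image(canvas), sigma = sigma)
    matrix(EBImage::imageData(img), nr, nc)
  }

  ch1 <- pmax(blur(deposit(truth$angular_truth_ch1, sig1), sig1), 0) +
    cfg$background_level
  ch2 <- pmax(blur(deposit(truth$angular_truth_ch2, sig2), sig2), 0) +
    cfg$background_level

  n <- nrow(rings)
  rnd <- with_seed(cfg$rng_seed + 1001L, {
    out <- list(jit_row = stats::runif(n, -2, 2),
                jit_col = stats::runif(n, -2, 2))
    if (noise) {
      out$ch1 <- matrix(stats::rpois(length(ch1), ch1), nr, nc)
      out$ch2 <- matrix(stats::rpois(length(ch2), ch2), nr, nc)
    }
    out
  })
  if (noise) { ch1 <- rnd$ch1; ch2 <- rnd$ch2 }
  centers <- data.frame(image_id = image_id, cell_id = rings$cell_id,
                        ring_id = rings$ring_id,
                        row_px = rings$center_row + rnd$jit_row,
                        col_px = rings$center_col + rnd$jit_col,
                        stringsAsFactors = FALSE)

  list(ch1 = image_plane(ch1, cfg$pixel_size_nm, "membrane", "sted"),
       ch2 = image_plane(ch2, cfg$pixel_size_nm, "companion", "confocal"),
       centers = centers)
}
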