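# Fixture builders shared across the test files. Everything is generated
# in code; no image files ship with the package.

# A raster with an ideal one-pixel-wide circle of uniform intensity.
ideal_ring_image <- function(size = 101L, center = c(50, 50), radius = 10,
                             intensity = 100, pixel_size_nm = 20) {
  m <- matrix(0, size, size)
  n_dep <- 16L * ceiling(2 * pi * radius)
  th <- seq(0, 2 * pi, length.out = n_dep + 1L)[seq_len(n_dep)]
  rr <- center[1] + radius * cos(th)
  cc <- center[2] + radius * sin(th)
  i0 <- floor(rr); j0 <- floor(cc); fr <- rr - i0; fc <- cc - j0
  lin <- c(j0 * size + i0 + 1L, j0 * size + i0 + 2L,
           (j0 + 1L) * size + i0 + 1L, (j0 + 1L) * size + i0 + 2L)
  w <- c((1 - fr) * (1 - fc), fr * (1 - fc), (1 - fr) * fc, fr * fc)
  agg <- rowsum(w, lin)
  m[as.integer(rownames(agg))] <- agg[, 1]
  m <- m / max(m) * intensity
  image_plane(m, pixel_size_nm, "ideal", "sted")
}

# An isotropic Gaussian spot (a sub-resolution organelle).
gaussian_spot_image <- function(size = 61L, center = c(30, 30), sigma = 2,
                                amplitude = 100, pixel_size_nm = 20) {
  r <- 0:(size - 1)
  m <- amplitude * exp(-outer((r - center[1])^2, (r - center[2])^2, `+`) /
                         (2 * sigma^2))
  image_plane(m, pixel_size_nm, "spot", "sted")
}

# A filled uniform disk.
disk_image <- function(size = 61L, center = c(30, 30), radius = 5,
                       intensity = 100, pixel_size_nm = 20) {
  r <- 0:(size - 1)
  d2 <- outer((r - center[1])^2, (r - center[2])^2, `+`)
  m <- matrix(0, size, size)
  m[d2 <= radius^2] <- intensity
  image_plane(m, pixel_size_nm, "disk", "sted")
}

# One small rendered scene with a single isolated ring.
single_ring_scene <- function(seed, radius_nm = NULL, noise = FALSE, ...) {
  args <- list(image_size_px = c(120L, 120L), n_cells = 1L,
               rings_per_cell_range = c(1L, 1L), cluster_probability = 0,
               rng_seed = seed, ...)
  if (!is.null(radius_nm)) args$radius_range_nm <- c(radius_nm, radius_nm)
  cfg <- do.call(scene_config, args)
  truth <- generate_scene(cfg)
  list(truth = truth, rendered = render_scene(truth, noise = noise))
}

# Bare-bones circle descriptors accepted by label_arc_samples().
circle_fit_stub <- function(center, radius_px, pixel_size_nm = 20, id = NA) {
  list(ring_id = id, center = center, radius_px = radius_px,
       radius_nm = radius_px * pixel_size_nm,
       circumference_nm = 2 * pi * radius_px * pixel_size_nm,
       pixel_size_nm = pixel_size_nm, method = "radial_peak",
       n_points = NA_integer_, quality = "ok")
}

# Rotate a raster 90 degrees counterclockwise in 0-based (row, col)
# convention: pixel (i, j) moves to (j, nrow - 1 - i).
rot90_matrix <- function(m) t(m)[, nrow(m):1, drop = FALSE]
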