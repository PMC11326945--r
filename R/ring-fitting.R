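#' Ring-fitting configuration
#'
#' Parameters controlling the peak-based circle fit. Defaults follow the
#' published procedure where it is explicit (10% relative-deviation outlier
#' exclusion) and documented choices where it is not (ray count, radial
#' search range, dip criterion for the small-ring fallback).
#'
#' @param n_rays number of equally spaced rays shot from the center.
#' @param r_min_px,r_max_px radial search range, pixels.
#' @param radial_step_px radial sampling step along each ray, pixels.
#' @param outlier_fraction relative deviation from the mean peak radius above
#'   which a peak is excluded (`0.10` = the >10% rule).
#' @param refit_iterations number of detect/exclude/fit rounds; after each
#'   round rays are re-shot from the refined center.
#' @param dip_ratio if the interpolated intensity at the seed center is at
#'   least `dip_ratio` times the mean retained peak intensity, the structure
#'   has no clear central dip and the segmentation fallback is used.
#' @param fallback_threshold_mode `"otsu"` or `"fraction_of_max"` threshold
#'   for the fallback segmentation.
#' @param min_retained_rays below this number of surviving peaks the fit is
#'   flagged `low_support`.
#' @param background_sigma a ray is retained only if its peak exceeds the
#'   local background median by this many background MADs. The default 5
#'   accounts for the peak being a maximum over ~dozens of radial samples:
#'   a milder cutoff would "detect" pure shot noise.
#' @param psf_fwhm_nm optional FWHM of the membrane channel's PSF. The
#'   radial peak of a Gaussian-blurred circle sits inward of the true
#'   radius (at the root of `r = a I1(ra/s^2)/I0(ra/s^2)`), a bias of
#'   roughly `s^2/(2a)` that matters for rings near the resolution limit.
#'   When the FWHM is known, the fitted radius is corrected by inverting
#'   this relation; `NULL` (default) applies no correction.
#'
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(n_rays = 360L, r_min_px = 1, r_max_px = 20,
                       radial_step_px = 0.25, outlier_fraction = 0.10,
                       refit_iterations = 2L, dip_ratio = 0.7,
                       fallback_threshold_mode = c("otsu", "fraction_of_max"),
                       min_retained_rays = 12L, background_sigma = 5,
                       psf_fwhm_nm = NULL) {
  fallback_threshold_mode <- match.arg(fallback_threshold_mode)
  if (r_min_px >= r_max_px)
    stop_typed("validation_error", "r_min_px must be < r_max_px")
  if (outlier_fraction <= 0 || outlier_fraction >= 1)
    stop_typed("validation_error", "outlier_fraction must lie in (0, 1)")
  if (dip_ratio <= 0 || dip_ratio > 1)
    stop_typed("validation_error", "dip_ratio must lie in (0, 1]")
  structure(list(n_rays = as.integer(n_rays), r_min_px = r_min_px,
                 r_max_px = r_max_px, radial_step_px = radial_step_px,
                 outlier_fraction = outlier_fraction,
                 refit_iterations = as.integer(refit_iterations),
                 dip_ratio = dip_ratio,
                 fallback_threshold_mode = fallback_threshold_mode,
                 min_retained_rays = as.integer(min_retained_rays),
                 background_sigma = background_sigma,
                 psf_fwhm_nm = psf_fwhm_nm),
            class = "fit_config")
}

new_polar_peak_set <- function(center, angles, radius_px, intensity, retained) {
  structure(list(center_used = center, angles = angles, radius_px = radius_px,
                 intensity = intensity, retained = retained),
            class = "polar_peak_set")
}

#' Detect membrane peak positions along rays from a seed center
#'
#' Shoots `n_rays` equally spaced rays from `center`, samples the radial
#' intensity profile of the membrane channel by bilinear interpolation
#' between `r_min_px` and `r_max_px`, and takes each ray's global maximum
#' with parabolic sub-step refinement as that ray's membrane peak. Rays
#' whose peak intensity does not rise above the local background (median
#' plus twice the MAD of an annulus outside the search range) are marked
#' non-retained.
#'
#' @param image an [image_plane()] (the high-resolution membrane channel).
#' @param center numeric `(row, col)`, 0-based continuous seed position.
#' @param config a [fit_config()].
#'
#' @return A `polar_peak_set` with per-ray angle, peak radius (px), peak
#'   intensity and retention flag.
#' @export
detect_peak_points <- function(image, center, config = fit_config()) {
  px <- image$pixels
  nr <- nrow(px); nc <- ncol(px)
  if (length(center) != 2L || anyNA(center))
    stop_typed("validation_error", "center must be a numeric (row, col) pair")
  rmax <- config$r_max_px
  if (center[1] < rmax || center[1] > nr - 1 - rmax ||
      center[2] < rmax || center[2] > nc - 1 - rmax)
    stop_typed("bounds_error",
               "center (%.1f, %.1f) closer than r_max_px = %.1f px to the image edge",
               center[1], center[2], rmax)

  theta <- angle_grid(config$n_rays)
  radii <- seq(config$r_min_px, rmax, by = config$radial_step_px)
  ns <- length(radii)
  rows <- center[1] + outer(cos(theta), radii)
  cols <- center[2] + outer(sin(theta), radii)
  prof <- matrix(bilinear_sample(px, as.vector(rows), as.vector(cols)),
                 nrow = config$n_rays)

  imax <- max.col(replace(prof, is.na(prof), -Inf), ties.method = "first")
  ## sub-step refinement: dense rescan of the interpolated profile around
  ## the coarse maximum (the bilinear interpolant is only piecewise smooth,
  ## so a local fine grid beats a single parabola), then a parabolic step
  ## on the fine grid
  fine_step <- config$radial_step_px / 25
  offs <- seq(-config$radial_step_px, config$radial_step_px, by = fine_step)
  rfine <- outer(radii[imax], rep(1, length(offs))) +
    matrix(offs, config$n_rays, length(offs), byrow = TRUE)
  rfine <- pmin(pmax(rfine, config$r_min_px), rmax)
  proff <- matrix(bilinear_sample(px,
                                  as.vector(rfine * cos(theta)) + center[1],
                                  as.vector(rfine * sin(theta)) + center[2]),
                  nrow = config$n_rays)
  jmax <- max.col(replace(proff, is.na(proff), -Inf), ties.method = "first")
  sel <- cbind(seq_len(config$n_rays), jmax)
  peak_int <- proff[sel]
  peak_r <- rfine[sel]
  interior <- which(jmax > 1L & jmax < length(offs))
  for (i in interior) {
    k <- jmax[i]
    off <- parabolic_offset(proff[i, k - 1L], proff[i, k], proff[i, k + 1L])
    peak_r[i] <- peak_r[i] + off * fine_step
  }

  ## local background from an annulus at 1.2-1.5 x r_max (clipped to image)
  bw <- ceiling(1.5 * rmax)
  ri <- max(0, floor(center[1] - bw)):min(nr - 1, ceiling(center[1] + bw))
  ci <- max(0, floor(center[2] - bw)):min(nc - 1, ceiling(center[2] + bw))
  dd <- sqrt(outer((ri - center[1])^2, (ci - center[2])^2, `+`))
  ann <- px[ri + 1, ci + 1, drop = FALSE][dd >= 1.2 * rmax & dd <= 1.5 * rmax]
  bg_med <- if (length(ann)) stats::median(ann) else 0
  bg_mad <- if (length(ann)) stats::mad(ann) else 0

  retained <- is.finite(peak_int) &
    peak_int > bg_med + config$background_sigma * bg_mad
  if (!any(retained))
    stop_typed("no_signal_error",
               "no ray peak rises above background at (%.1f, %.1f)",
               center[1], center[2])
  new_polar_peak_set(center, theta, peak_r, peak_int, retained)
}

#' Exclude outlier membrane peaks by relative deviation from the mean radius
#'
#' Single pass: the mean radius of currently retained peaks is computed
#' once, and every peak deviating from it by more than `outlier_fraction`
#' (relative) is un-retained. The input object is not modified.
#'
#' @param peaks a `polar_peak_set` from [detect_peak_points()].
#' @param outlier_fraction maximum allowed relative deviation (default 0.10,
#'   i.e. peaks deviating by more than 10% from the mean distance to the
#'   center are excluded).
#'
#' @return A new `polar_peak_set` with outliers un-retained.
#' @export
exclude_outlier_peaks <- function(peaks, outlier_fraction = 0.10) {
  if (sum(peaks$retained) < 3L)
    stop_typed("validation_error", "need at least 3 retained peaks")
  r <- peaks$radius_px
  m <- mean(r[peaks$retained])
  keep <- peaks$retained & abs(r - m) / m <= outlier_fraction
  new_polar_peak_set(peaks$center_used, peaks$angles, r, peaks$intensity, keep)
}

#' Algebraic (Kasa) least-squares circle fit
#'
#' Fits a circle to 2D points by linear least squares on
#' `2a*row + 2b*col + c = row^2 + col^2`; exact for points lying on a true
#' circle.
#'
#' @param points numeric matrix with columns `(row, col)`, at least 3
#'   non-collinear rows.
#'
#' @return A list with `center` (row, col) and `radius`.
#' @export
fit_circle_lsq <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3L)
    stop_typed("degenerate_geometry_error", "need at least 3 points")
  A <- cbind(2 * points[, 1], 2 * points[, 2], 1)
  b <- points[, 1]^2 + points[, 2]^2
  qrA <- qr(A)
  if (qrA$rank < 3L)
    stop_typed("degenerate_geometry_error", "points are collinear")
  sol <- qr.coef(qrA, b)
  center <- sol[1:2]
  rad2 <- sol[3] + sum(center^2)
  if (!is.finite(rad2) || rad2 <= 0)
    stop_typed("degenerate_geometry_error", "circle fit produced nonpositive radius")
  list(center = unname(center), radius = sqrt(rad2))
}

## Radial peak position of a circle of radius a under isotropic Gaussian
## blur sigma: fixed point of r = a I1(ra/sigma^2) / I0(ra/sigma^2).
ring_peak_radius <- function(a, sigma) {
  r <- a
  for (i in 1:200) {
    x <- r * a / sigma^2
    r_new <- a * besselI(x, 1, expon.scaled = TRUE) /
      besselI(x, 0, expon.scaled = TRUE)
    if (abs(r_new - r) < 1e-10) return(r_new)
    r <- r_new
  }
  r
}

## Invert the blur-induced inward shift of the observed peak radius.
correct_peak_radius <- function(r_obs, sigma) {
  sol <- tryCatch(
    stats::uniroot(function(a) ring_peak_radius(a, sigma) - r_obs,
                   lower = r_obs, upper = r_obs + max(2 * sigma, 1),
                   tol = 1e-9, extendInt = "upX"),
    error = function(e) NULL)
  if (is.null(sol)) r_obs else sol$root
}

## Robust initial circle from peak points: deterministic consensus over
## well-conditioned (~120 degree spaced) point triplets. Points locked
## onto a neighbouring ring's crest are angularly localised and carry
## high leverage in an algebraic fit; the consensus fit ignores them.
init_circle_robust <- function(pts, r_min, r_max, inlier_tol = 0.5) {
  n <- nrow(pts)
  if (n < 3L) return(NULL)
  third <- max(1L, round(n / 3))
  starts <- unique(round(seq(1L, third, length.out = min(24L, third))))
  ok_radius <- function(f) f$radius >= r_min && f$radius <= r_max
  best <- NULL; best_n <- -1L; best_in <- NULL
  for (s in starts) {
    tri <- ((s - 1L + c(0L, third, 2L * third)) %% n) + 1L
    if (length(unique(tri)) < 3L) next
    f <- tryCatch(fit_circle_lsq(pts[tri, , drop = FALSE]),
                  stedrings_error = function(e) NULL)
    if (is.null(f) || !ok_radius(f)) next
    d <- abs(sqrt((pts[, 1] - f$center[1])^2 +
                  (pts[, 2] - f$center[2])^2) - f$radius)
    inl <- d <= inlier_tol
    if (sum(inl) > best_n) { best_n <- sum(inl); best <- f; best_in <- inl }
  }
  if (is.null(best)) return(NULL)
  if (best_n >= 3L) {
    refit <- tryCatch(fit_circle_lsq(pts[best_in, , drop = FALSE]),
                      stedrings_error = function(e) NULL)
    if (!is.null(refit) && ok_radius(refit)) best <- refit
  }
  best
}

new_ring_fit_result <- function(center, radius_px, pixel_size_nm, method,
                                n_points, n_rays, quality = "ok") {
  radius_nm <- radius_px * pixel_size_nm
  structure(list(center = center, radius_px = radius_px,
                 radius_nm = radius_nm,
                 circumference_nm = 2 * pi * radius_nm,
                 method = method, n_points = n_points, n_rays = n_rays,
                 pixel_size_nm = pixel_size_nm, quality = quality),
            class = "ring_fit_result")
}

#' @export
print.ring_fit_result <- function(x, ...) {
  cat(sprintf("<ring_fit_result> center (%.2f, %.2f) px, r = %.2f px (%.1f nm), C = %.1f nm, %s [%s]\n",
              x$center[1], x$center[2], x$radius_px, x$radius_nm,
              x$circumference_nm, x$method, x$quality))
  invisible(x)
}

#' Segmentation fallback for small filled structures
#'
#' For organelles below the resolution limit the membrane shows no central
#' intensity dip and a radial peak fit is meaningless. The fallback
#' thresholds a local window around the seed (Otsu or half-maximum), takes
#' the connected component at (or nearest to) the seed, and reports the
#' intensity-weighted centroid and half the major-axis length from second
#' central moments as the circle.
#'
#' @inheritParams detect_peak_points
#' @return A `ring_fit_result` with `method = "segmentation_fallback"`.
#' @export
segment_fallback <- function(image, center, config = fit_config()) {
  px <- image$pixels
  nr <- nrow(px); nc <- ncol(px)
  w <- ceiling(config$r_max_px + 2)
  ri <- max(0, floor(center[1] - w)):min(nr - 1, ceiling(center[1] + w))
  ci <- max(0, floor(center[2] - w)):min(nc - 1, ceiling(center[2] + w))
  win <- px[ri + 1, ci + 1, drop = FALSE]
  mx <- max(win)
  if (mx <= 0)
    stop_typed("no_signal_error", "all-zero window around seed (%.1f, %.1f)",
               center[1], center[2])
  thr <- switch(config$fallback_threshold_mode,
                otsu = EBImage::otsu(EBImage::Image(win / mx), range = c(0, 1)) * mx,
                fraction_of_max = 0.5 * mx)
  mask <- win > thr
  if (!any(mask))
    stop_typed("no_signal_error", "empty segmentation around seed (%.1f, %.1f)",
               center[1], center[2])
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- matrix(as.integer(EBImage::imageData(lab)), nrow = nrow(win))
  ## component containing the seed, else the nearest one
  sr <- round(center[1]) - ri[1] + 1; sc <- round(center[2]) - ci[1] + 1
  sel <- 0L
  if (sr >= 1 && sr <= nrow(lab) && sc >= 1 && sc <= ncol(lab))
    sel <- lab[sr, sc]
  if (sel == 0L) {
    idx <- which(lab > 0L, arr.ind = TRUE)
    d2 <- (idx[, 1] - sr)^2 + (idx[, 2] - sc)^2
    sel <- lab[idx[which.min(d2), , drop = FALSE]]
  }
  comp <- which(lab == sel, arr.ind = TRUE)
  wts <- win[comp]
  rows0 <- ri[comp[, 1]]          # back to 0-based image coordinates
  cols0 <- ci[comp[, 2]]
  cen <- c(sum(rows0 * wts), sum(cols0 * wts)) / sum(wts)
  dr <- rows0 - cen[1]; dc <- cols0 - cen[2]
  cov <- matrix(c(sum(wts * dr * dr), sum(wts * dr * dc),
                  sum(wts * dr * dc), sum(wts * dc * dc)), 2) / sum(wts)
  lam <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values[1]
  radius_px <- 2 * sqrt(max(lam, 0))
  if (radius_px <= 0)
    stop_typed("no_signal_error", "degenerate single-pixel segmentation")
  new_ring_fit_result(cen, radius_px, image$pixel_size_nm,
                      "segmentation_fallback", NA_integer_, config$n_rays)
}

#' Fit a circle to one membrane ring
#'
#' Full per-organelle fit: peaks are detected from the seed, a central-dip
#' test decides between the radial-peak route and the segmentation
#' fallback, outlier peaks (relative deviation above `outlier_fraction`)
#' are excluded, and a least-squares circle is fitted; the detect/exclude/
#' fit round is repeated `refit_iterations` times, re-shooting rays from
#' the refined center. The circumference is `2 * pi * radius_nm`.
#'
#' @inheritParams detect_peak_points
#' @param seed numeric `(row, col)` approximate center (e.g. a manual click).
#'
#' @return A `ring_fit_result`.
#' @export
fit_ring <- function(image, seed, config = fit_config()) {
  peaks <- detect_peak_points(image, seed, config)

  ## Initialisation: fit all retained peak points without exclusion. The
  ## peak points lie on the membrane circle regardless of how far the
  ## manual seed sits from the true center, whereas radii *from the seed*
  ## spread with the click offset — so deviation-based exclusion is only
  ## meaningful once rays emanate from an approximately correct center.
  idx0 <- which(peaks$retained)
  pts0 <- cbind(seed[1] + peaks$radius_px[idx0] * cos(peaks$angles[idx0]),
                seed[2] + peaks$radius_px[idx0] * sin(peaks$angles[idx0]))
  init <- init_circle_robust(pts0, config$r_min_px, config$r_max_px)
  center <- if (is.null(init)) seed else init$center

  ## dip test at the initial center: a filled sub-resolution spot has no
  ## clear central intensity dip and goes to the segmentation fallback
  cen_int <- bilinear_sample(image$pixels, center[1], center[2])
  mean_peak <- mean(peaks$intensity[peaks$retained])
  if (is.finite(cen_int) && cen_int >= config$dip_ratio * mean_peak)
    return(segment_fallback(image, seed, config))

  quality <- "ok"
  fit <- NULL
  for (iter in seq_len(max(1L, config$refit_iterations))) {
    peaks <- detect_peak_points(image, center, config)
    kept <- exclude_outlier_peaks(peaks, config$outlier_fraction)
    ## In a tight cluster, rays crossing a neighbouring ring can lock onto
    ## its (farther, often brighter) membrane crest; the mean peak radius
    ## then sits between the two populations and the deviation band around
    ## it retains a small, wrong minority. The same band around the median
    ## (breakdown 50% instead of 0%) is used whenever it retains more
    ## rays; on clean data the two retain essentially the same set.
    med <- stats::median(peaks$radius_px[peaks$retained])
    keep_med <- peaks$retained &
      abs(peaks$radius_px - med) / med <= config$outlier_fraction
    if (sum(keep_med) > sum(kept$retained)) kept$retained <- keep_med
    n_kept <- sum(kept$retained)
    if (n_kept < config$min_retained_rays) quality <- "low_support"
    if (n_kept < 3L) return(segment_fallback(image, seed, config))
    idx <- which(kept$retained)
    pts <- cbind(center[1] + kept$radius_px[idx] * cos(kept$angles[idx]),
                 center[2] + kept$radius_px[idx] * sin(kept$angles[idx]))
    new_fit <- tryCatch(fit_circle_lsq(pts), stedrings_error = function(e) NULL)
    if (is.null(new_fit) ||
        new_fit$radius < config$r_min_px || new_fit$radius > config$r_max_px) {
      ## degenerate or out-of-range iterate: keep the previous estimate
      ## (or the initialisation) rather than diverge
      if (!is.null(fit)) break
      if (!is.null(init)) { fit <- init; n_points <- n_kept; break }
      return(segment_fallback(image, seed, config))
    }
    fit <- new_fit
    center <- fit$center
    n_points <- n_kept
  }
  radius <- fit$radius
  if (!is.null(config$psf_fwhm_nm)) {
    sigma_px <- config$psf_fwhm_nm / (2 * sqrt(2 * log(2))) /
      image$pixel_size_nm
    radius <- correct_peak_radius(radius, sigma_px)
  }
  new_ring_fit_result(fit$center, radius, image$pixel_size_nm,
                      "radial_peak", n_points, config$n_rays, quality)
}
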