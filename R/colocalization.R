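#' Circular moving average
#'
#' Smooths a periodic sequence (a membrane profile) with a centered
#' moving-average window that wraps around, so the sequence mean is
#' preserved exactly.
#'
#' @param values numeric vector (one period of a periodic signal).
#' @param window odd window length, `1 <= window <= length(values)`.
#'
#' @return Numeric vector of the same length.
#' @export
moving_average_circular <- function(values, window) {
  k <- length(values)
  if (length(window) != 1L || window != as.integer(window) || !is_odd(window) ||
      window < 1L || window > k)
    stop_typed("validation_error",
               "window must be an odd integer in [1, %d]", k)
  if (window == 1L) return(values)
  as.numeric(stats::filter(values, rep(1 / window, window),
                           method = "convolution", sides = 2,
                           circular = TRUE))
}

#' Pearson product-moment correlation with an explicit undefined flag
#'
#' @param a,b numeric vectors of equal length `K >= 3`.
#' @return The correlation coefficient, or `NA` when either input has zero
#'   variance (undefined, never silently zero).
#' @export
pearson_r <- function(a, b) {
  if (length(a) != length(b))
    stop_typed("validation_error", "inputs differ in length (%d vs %d)",
               length(a), length(b))
  if (length(a) < 3L)
    stop_typed("validation_error", "need at least 3 samples")
  if (stats::var(a) == 0 || stats::var(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

#' Per-organelle moving-average correlation between the two channels
#'
#' The colocalization statistic reported per peroxisome: both membrane
#' profiles are smoothed with the same circular moving average and the
#' Pearson correlation of the smoothed sequences is returned.
#'
#' @param profile a `membrane_profile` from [extract_dual_profiles()].
#' @param window odd moving-average window (default 5 samples).
#'
#' @return A `correlation_result` with fields `ring_id`, `R` (NA when
#'   undefined), `window`, `n_samples`.
#' @export
ring_correlation <- function(profile, window = 5L) {
  s1 <- moving_average_circular(profile$intensities_ch1, window)
  s2 <- moving_average_circular(profile$intensities_ch2, window)
  structure(list(ring_id = profile$ring_id,
                 R = pearson_r(s1, s2),
                 window = as.integer(window),
                 n_samples = length(s1)),
            class = "correlation_result")
}
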