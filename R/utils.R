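## Internal numeric helpers shared across the pipeline.

## Vectorized bilinear interpolation on a matrix, 0-based continuous
## coordinates with pixel centers at integers. Points outside the raster
## return NA (callers decide whether that is an error).
bilinear_sample <- function(pixels, row, col) {
  nr <- nrow(pixels); nc <- ncol(pixels)
  out <- rep(NA_real_, length(row))
  ok <- row >= 0 & row <= nr - 1 & col >= 0 & col <= nc - 1 &
    is.finite(row) & is.finite(col)
  if (!any(ok)) return(out)
  r <- row[ok]; c <- col[ok]
  i0 <- pmin(floor(r), nr - 2); j0 <- pmin(floor(c), nc - 2)
  fr <- r - i0; fc <- c - j0
  ## 1-based matrix indexing under the hood
  i1 <- i0 + 1; j1 <- j0 + 1
  v00 <- pixels[cbind(i1, j1)]
  v10 <- pixels[cbind(i1 + 1, j1)]
  v01 <- pixels[cbind(i1, j1 + 1)]
  v11 <- pixels[cbind(i1 + 1, j1 + 1)]
  out[ok] <- v00 * (1 - fr) * (1 - fc) + v10 * fr * (1 - fc) +
    v01 * (1 - fr) * fc + v11 * fr * fc
  out
}

## Parabolic (3-point) refinement of a discrete maximum. Returns the
## sub-step offset in units of the grid step, clamped to [-0.5, 0.5].
parabolic_offset <- function(ym1, y0, yp1) {
  denom <- ym1 - 2 * y0 + yp1
  if (!is.finite(denom) || abs(denom) < .Machine$double.eps) return(0)
  off <- 0.5 * (ym1 - yp1) / denom
  max(-0.5, min(0.5, off))
}

## Condition-typed errors so callers can distinguish validation problems
## from absent signal or degenerate geometry.
stop_typed <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(class = c(class, "stedrings_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

is_odd <- function(x) x %% 2 == 1

## K angles uniformly spaced on [0, 2pi), starting at 0.
angle_grid <- function(k) seq(0, 2 * pi, length.out = k + 1)[seq_len(k)]
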