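#' Single-channel image plane
#'
#' Container for one 2D grayscale raster together with its physical pixel
#' size and channel identity. All pipeline coordinates are 0-based
#' continuous `(row, col)` with pixel centers at integer coordinates, so a
#' point at `(row, col)` sits `row * pixel_size_nm` nanometres from the top
#' edge of the image.
#'
#' @param pixels numeric matrix of nonnegative intensities.
#' @param pixel_size_nm physical edge length of one pixel, in nanometres.
#' @param channel_name free-text channel label (e.g. `"Pex3-Halo"`).
#' @param resolution_class `"sted"` or `"confocal"`; used by profile
#'   extraction to pick the sampling band width.
#'
#' @return An object of class `image_plane`.
#' @export
image_plane <- function(pixels, pixel_size_nm, channel_name = "ch",
                        resolution_class = c("sted", "confocal")) {
  resolution_class <- match.arg(resolution_class)
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  if (anyNA(pixels) || any(pixels < 0))
    stop("`pixels` must be nonnegative and free of NA", call. = FALSE)
  if (!is.numeric(pixel_size_nm) || length(pixel_size_nm) != 1L ||
      pixel_size_nm <= 0)
    stop("`pixel_size_nm` must be a single positive number", call. = FALSE)
  structure(
    list(pixels = pixels, pixel_size_nm = pixel_size_nm,
         channel_name = channel_name, resolution_class = resolution_class),
    class = "image_plane"
  )
}

#' @export
print.image_plane <- function(x, ...) {
  cat(sprintf("<image_plane> %s [%s], %d x %d px @ %.3g nm/px\n",
              x$channel_name, x$resolution_class,
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_nm))
  invisible(x)
}

#' @export
dim.image_plane <- function(x) dim(x$pixels)

## Check that two planes can be analysed jointly (same raster grid).
assert_congruent <- function(a, b) {
  if (!identical(dim(a$pixels), dim(b$pixels)))
    stop_typed("congruence_error", "raster sizes differ: %s vs %s",
               paste(dim(a$pixels), collapse = "x"),
               paste(dim(b$pixels), collapse = "x"))
  if (abs(a$pixel_size_nm - b$pixel_size_nm) > 1e-9)
    stop_typed("congruence_error", "pixel sizes differ between channels")
  invisible(TRUE)
}
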