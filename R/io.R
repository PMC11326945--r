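SCHEMA_VERSION <- "stedrings-tables-v1"

#' Write a rendered scene to disk (TIFF pair + centers CSV + truth JSON)
#'
#' Channels are written as single-plane 16-bit grayscale TIFFs (photon
#' counts, clipped at 65535), the pixel size goes into a JSON sidecar, the
#' (jittered) centers into a CSV with header
#' `image_id,cell_id,ring_id,row_px,col_px`, and the ground truth (ring
#' geometry, angular truths, planted labels, config) into a JSON document.
#'
#' @param rendered output of [render_scene()].
#' @param truth the matching `scene_ground_truth` (optional; skip to omit
#'   the truth file).
#' @param dir output directory (created if needed).
#' @param image_id file stem.
#' @return Invisibly, the named vector of paths written.
#' @export
write_scene <- function(rendered, truth = NULL, dir, image_id = "scene") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(ch1 = file.path(dir, paste0(image_id, "_ch1.tif")),
             ch2 = file.path(dir, paste0(image_id, "_ch2.tif")),
             meta = file.path(dir, paste0(image_id, "_meta.json")),
             centers = file.path(dir, paste0(image_id, "_centers.csv")))
  to16 <- function(m) pmin(round(m), 65535) / 65535
  tiff::writeTIFF(to16(rendered$ch1$pixels), paths["ch1"],
                  bits.per.sample = 16L, compression = "none")
  tiff::writeTIFF(to16(rendered$ch2$pixels), paths["ch2"],
                  bits.per.sample = 16L, compression = "none")
  jsonlite::write_json(
    list(schema = SCHEMA_VERSION,
         pixel_size_nm = rendered$ch1$pixel_size_nm,
         channels = list(ch1 = list(name = rendered$ch1$channel_name,
                                    resolution_class = rendered$ch1$resolution_class),
                         ch2 = list(name = rendered$ch2$channel_name,
                                    resolution_class = rendered$ch2$resolution_class))),
    paths["meta"], auto_unbox = TRUE, digits = NA)
  utils::write.csv(rendered$centers, paths["centers"], row.names = FALSE)
  if (!is.null(truth)) {
    paths <- c(paths, truth = file.path(dir, paste0(image_id, "_truth.json")))
    jsonlite::write_json(
      list(schema = SCHEMA_VERSION, rings = truth$rings,
           angles = truth$angles,
           angular_truth_ch1 = truth$angular_truth_ch1,
           angular_truth_ch2 = truth$angular_truth_ch2,
           expected_labels = truth$expected_labels,
           params = unclass(truth$params)),
      paths["truth"], auto_unbox = TRUE, digits = NA)
  }
  invisible(paths)
}

read_tiff_plane <- function(path) {
  if (!file.exists(path))
    stop_typed("format_error", "TIFF file not found: %s", path)
  planes <- tiff::readTIFF(path, all = TRUE)
  if (length(planes) != 1L)
    stop_typed("format_error", "%s has %d planes; expected a single plane",
               path, length(planes))
  m <- planes[[1]]
  if (length(dim(m)) == 3L) {
    if (dim(m)[3] > 1L)
      stop_typed("format_error", "%s is not single-channel grayscale", path)
    m <- m[, , 1]
  }
  round(m * 65535)
}

#' Read a congruent two-channel image pair from TIFF
#'
#' @param ch1_path,ch2_path single-plane grayscale TIFF paths (membrane /
#'   companion channel).
#' @param pixel_size_nm explicit pixel size; overrides the sidecar.
#' @param meta_path JSON sidecar holding `pixel_size_nm` (defaults to the
#'   `*_meta.json` next to `ch1_path`). One of the two sources must
#'   provide the pixel size.
#' @return List of two congruent [image_plane()]s.
#' @export
read_image_pair <- function(ch1_path, ch2_path, pixel_size_nm = NULL,
                            meta_path = NULL) {
  m1 <- read_tiff_plane(ch1_path)
  m2 <- read_tiff_plane(ch2_path)
  if (is.null(meta_path))
    meta_path <- sub("_ch1\\.tif{1,2}$", "_meta.json", ch1_path)
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else NULL
  if (is.null(pixel_size_nm)) pixel_size_nm <- meta$pixel_size_nm
  if (is.null(pixel_size_nm))
    stop_typed("configuration_error",
               "no pixel size: provide pixel_size_nm or a metadata sidecar for %s",
               ch1_path)
  ch1 <- image_plane(m1, pixel_size_nm,
                     channel_name = meta$channels$ch1$name %||% "ch1",
                     resolution_class = meta$channels$ch1$resolution_class %||% "sted")
  ch2 <- image_plane(m2, pixel_size_nm,
                     channel_name = meta$channels$ch2$name %||% "ch2",
                     resolution_class = meta$channels$ch2$resolution_class %||% "confocal")
  assert_congruent(ch1, ch2)
  list(ch1 = ch1, ch2 = ch2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a manual ring-centers table
#'
#' Expects a CSV with header `image_id,cell_id,row_px,col_px` (an optional
#' `ring_id` column is preserved). Coordinates are 0-based pixels; bounds
#' are checked later, at fit time. Duplicate `(image_id, row_px, col_px)`
#' rows are dropped with a warning.
#'
#' @param path CSV path.
#' @return Validated data.frame of seed annotations.
#' @export
read_centers <- function(path) {
  if (!file.exists(path))
    stop_typed("format_error", "centers file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("image_id", "cell_id", "row_px", "col_px")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_typed("format_error", "centers file %s lacks columns: %s",
               path, paste(miss, collapse = ", "))
  for (col in c("row_px", "col_px")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad))
      stop_typed("format_error",
                 "non-numeric %s in %s at line(s) %s", col, path,
                 paste(bad + 1L, collapse = ", "))  # +1 for the header line
    if (anyNA(v))
      stop_typed("format_error", "missing %s in %s at line(s) %s", col, path,
                 paste(which(is.na(v)) + 1L, collapse = ", "))
    df[[col]] <- v
  }
  key <- paste(df$image_id, df$row_px, df$col_px)
  if (anyDuplicated(key)) {
    warning(sprintf("read_centers: %d duplicate center row(s) dropped",
                    sum(duplicated(key))), call. = FALSE)
    df <- df[!duplicated(key), , drop = FALSE]
  }
  if (!"ring_id" %in% names(df)) df$ring_id <- seq_len(nrow(df))
  df
}

#' Read a run configuration (YAML or JSON)
#'
#' @param path configuration file; format decided by extension.
#' @return Named list of configuration values.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop_typed("format_error", "config file not found: %s", path)
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
}

## Results tables are written with a one-line schema-version comment so
## they can be validated on re-import (read with comment.char = "#").
write_result_table <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s", SCHEMA_VERSION), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}
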