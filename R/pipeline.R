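#' Analyse one two-channel image: fit, profile, correlate, classify
#'
#' Runs the full per-image chain for every seeded center: circle fit
#' ([fit_ring()]), dual-channel membrane profile
#' ([extract_dual_profiles()]), moving-average correlation
#' ([ring_correlation()]), contact labeling against all other fitted rings
#' in the image ([label_arc_samples()]) and Between/Outside class means.
#' Per-ring failures (seed on background, degenerate geometry, band outside
#' the image) are caught and recorded with a failure code; they never abort
#' the batch.
#'
#' @param ch1,ch2 congruent [image_plane()]s (membrane / companion).
#' @param centers data.frame with `cell_id`, `row_px`, `col_px` (plus
#'   optional `image_id`, `ring_id`).
#' @param fit_cfg,prof_cfg,contact_cfg stage configurations.
#' @param window odd moving-average window for the correlation.
#' @param image_id identifier stamped on output rows.
#'
#' @return List with `records` (one row per seed, failure-coded where
#'   needed), `fits`, `profiles`, `labelings`.
#' @export
analyze_image <- function(ch1, ch2, centers,
                          fit_cfg = fit_config(),
                          prof_cfg = profile_config(),
                          contact_cfg = contact_config(),
                          window = 5L, image_id = NULL) {
  assert_congruent(ch1, ch2)
  if (is.null(image_id))
    image_id <- if ("image_id" %in% names(centers)) centers$image_id[1] else "image"
  n <- nrow(centers)
  if (!"ring_id" %in% names(centers)) centers$ring_id <- seq_len(n)

  fits <- vector("list", n)
  failures <- character(n)
  for (i in seq_len(n)) {
    f <- tryCatch(
      fit_ring(ch1, c(centers$row_px[i], centers$col_px[i]), fit_cfg),
      stedrings_error = function(e) e)
    if (inherits(f, "stedrings_error")) {
      failures[i] <- class(f)[1]
      fits[i] <- list(NULL)
    } else {
      f$ring_id <- centers$ring_id[i]
      fits[[i]] <- f
    }
  }

  ok <- !vapply(fits, is.null, TRUE)
  valid_fits <- fits[ok]
  rows <- vector("list", n)
  profiles <- vector("list", n)
  labelings <- vector("list", n)
  for (i in seq_len(n)) {
    base <- data.frame(image_id = image_id, ring_id = centers$ring_id[i],
                       cell_id = centers$cell_id[i],
                       seed_row_px = centers$row_px[i],
                       seed_col_px = centers$col_px[i],
                       stringsAsFactors = FALSE)
    if (!ok[i]) {
      rows[[i]] <- cbind(base, data.frame(
        center_row_px = NA_real_, center_col_px = NA_real_,
        radius_px = NA_real_, radius_nm = NA_real_,
        circumference_nm = NA_real_, n_points = NA_integer_,
        method = NA_character_, quality = NA_character_,
        mean_ch1 = NA_real_, mean_ch2 = NA_real_, R = NA_real_,
        window = NA_integer_, mean_between_ch2 = NA_real_,
        mean_outside_ch2 = NA_real_, n_between = NA_integer_,
        n_outside = NA_integer_, failure = failures[i]))
      next
    }
    fit <- fits[[i]]
    res <- tryCatch({
      prof <- extract_dual_profiles(ch1, ch2, fit, prof_cfg,
                                    ring_id = centers$ring_id[i])
      corr <- ring_correlation(prof, window)
      lab <- label_arc_samples(fit, valid_fits, prof$angles, contact_cfg)
      bo <- between_outside_means(prof, lab)
      profiles[[i]] <- prof
      labelings[[i]] <- lab
      data.frame(center_row_px = fit$center[1], center_col_px = fit$center[2],
                 radius_px = fit$radius_px, radius_nm = fit$radius_nm,
                 circumference_nm = fit$circumference_nm,
                 n_points = fit$n_points, method = fit$method,
                 quality = fit$quality,
                 mean_ch1 = mean(prof$intensities_ch1),
                 mean_ch2 = mean(prof$intensities_ch2),
                 R = corr$R, window = corr$window,
                 mean_between_ch2 = bo$mean_between,
                 mean_outside_ch2 = bo$mean_outside,
                 n_between = bo$n_between, n_outside = bo$n_outside,
                 failure = "", stringsAsFactors = FALSE)
    }, stedrings_error = function(e) {
      data.frame(center_row_px = fit$center[1], center_col_px = fit$center[2],
                 radius_px = fit$radius_px, radius_nm = fit$radius_nm,
                 circumference_nm = fit$circumference_nm,
                 n_points = fit$n_points, method = fit$method,
                 quality = fit$quality, mean_ch1 = NA_real_,
                 mean_ch2 = NA_real_, R = NA_real_, window = NA_integer_,
                 mean_between_ch2 = NA_real_, mean_outside_ch2 = NA_real_,
                 n_between = NA_integer_, n_outside = NA_integer_,
                 failure = class(e)[1], stringsAsFactors = FALSE)
    })
    rows[[i]] <- cbind(base, res)
  }
  list(records = do.call(rbind, rows), fits = fits,
       profiles = profiles, labelings = labelings)
}

#' Run the full batch pipeline over an image manifest
#'
#' For every manifest entry the two channels are read, the image's seeds
#' are fitted and measured ([analyze_image()]), cells are classified by
#' their predominant companion-channel localisation, and condition-level
#' summaries and tests are computed ([summarize_conditions()]). Rows in
#' equal rows out: every seed yields exactly one per-peroxisome row, valid
#' or failure-coded.
#'
#' @param config named list (or path read via [read_run_config()]) with:
#'   `manifest` — data.frame `image_id, condition, replicate, ch1_path,
#'   ch2_path` (optional `pixel_size_nm`); `centers_path` — CSV of seeds;
#'   optional `fit`, `profile`, `contact` — argument lists for the stage
#'   configs; optional `window` (odd, default 5), `anova_level`,
#'   `paired_conditions`, `paired_direction`, `output_dir`.
#'
#' @return List of class `results_table`: `per_peroxisome`, `per_cell`,
#'   `summary`, `replicate_summary`, `outside`, `tests`. When `output_dir`
#'   is set the tables are also written as schema-versioned CSVs.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  manifest <- config$manifest
  if (is.null(manifest) || nrow(manifest) < 1L)
    stop_typed("validation_error", "empty image manifest")
  centers_all <- read_centers(config$centers_path)
  fit_cfg <- do.call(fit_config, config$fit %||% list())
  prof_cfg <- do.call(profile_config, config$profile %||% list())
  contact_cfg <- do.call(contact_config, config$contact %||% list())
  window <- config$window %||% 5L

  record_list <- list()
  cell_list <- list()
  for (k in seq_len(nrow(manifest))) {
    entry <- manifest[k, ]
    pair <- read_image_pair(entry$ch1_path, entry$ch2_path,
                            pixel_size_nm = entry$pixel_size_nm %||%
                              config$pixel_size_nm)
    centers <- centers_all[centers_all$image_id == entry$image_id, ,
                           drop = FALSE]
    if (!nrow(centers)) next
    res <- analyze_image(pair$ch1, pair$ch2, centers, fit_cfg, prof_cfg,
                         contact_cfg, window, image_id = entry$image_id)
    rec <- res$records
    rec$condition <- entry$condition
    rec$replicate <- entry$replicate
    record_list[[k]] <- rec
    valid <- rec[rec$failure == "", , drop = FALSE]
    for (cid in unique(valid$cell_id)) {
      cl <- classify_cell(within(valid[valid$cell_id == cid, , drop = FALSE], {
        condition <- entry$condition; replicate <- entry$replicate
      }))
      cl$image_id <- entry$image_id
      cell_list[[length(cell_list) + 1L]] <- cl
    }
  }
  records <- do.call(rbind, record_list)
  cells <- if (length(cell_list)) do.call(rbind, cell_list) else NULL
  valid_records <- records[records$failure == "", , drop = FALSE]
  stats_out <- summarize_conditions(
    valid_records, cells,
    anova_level = config$anova_level %||% "ring",
    paired_conditions = config$paired_conditions,
    paired_direction = config$paired_direction %||% "greater")

  out <- structure(list(per_peroxisome = records, per_cell = cells,
                        summary = stats_out$summary,
                        replicate_summary = stats_out$replicate_summary,
                        outside = stats_out$outside,
                        tests = stats_out$tests),
                   class = "results_table")
  if (!is.null(config$output_dir)) write_results(out, config$output_dir)
  out
}

#' Write a results table set to CSV
#'
#' @param results a `results_table` from [run_pipeline()].
#' @param dir output directory.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in c("per_peroxisome", "per_cell", "summary",
               "replicate_summary", "outside", "tests")) {
    df <- results[[nm]]
    if (is.null(df)) next
    p <- file.path(dir, paste0(nm, ".csv"))
    write_result_table(df, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Simulate a multi-condition synthetic study on disk
#'
#' Generates, renders and writes one scene per condition x replicate x
#' image, returning a ready-to-run pipeline config. Convenience wrapper
#' used by the bundled command-line script and the package's own
#' end-to-end checks.
#'
#' @param dir output directory.
#' @param conditions named list: for each condition label, a list of
#'   [scene_config()] overrides (e.g. `coupling_alpha`).
#' @param n_replicates replicates per condition.
#' @param images_per_replicate scenes per replicate.
#' @param base_seed integer; scene seeds are derived deterministically.
#' @param noise logical, Poisson noise on/off.
#' @param ... common [scene_config()] overrides applied to all conditions.
#'
#' @return The pipeline `config` list (manifest + centers path), with the
#'   ground truths attached as attribute `"truths"`.
#' @export
simulate_study <- function(dir, conditions, n_replicates = 2L,
                           images_per_replicate = 1L, base_seed = 1L,
                           noise = TRUE, ...) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  common <- list(...)
  manifest <- list(); centers <- list(); truths <- list()
  idx <- 0L
  for (ci in seq_along(conditions)) {
    cond <- names(conditions)[ci]
    for (rep_i in seq_len(n_replicates)) {
      for (im in seq_len(images_per_replicate)) {
        idx <- idx + 1L
        image_id <- sprintf("%s_r%d_i%d", cond, rep_i, im)
        args <- utils::modifyList(common, conditions[[ci]])
        args$rng_seed <- base_seed + 7L * idx
        cfg <- do.call(scene_config, args)
        truth <- generate_scene(cfg)
        rendered <- render_scene(truth, noise = noise, image_id = image_id)
        paths <- write_scene(rendered, truth, dir, image_id)
        manifest[[idx]] <- data.frame(
          image_id = image_id, condition = cond, replicate = rep_i,
          ch1_path = unname(paths["ch1"]), ch2_path = unname(paths["ch2"]),
          stringsAsFactors = FALSE)
        centers[[idx]] <- rendered$centers
        truths[[image_id]] <- truth
      }
    }
  }
  centers_path <- file.path(dir, "centers.csv")
  utils::write.csv(do.call(rbind, centers), centers_path, row.names = FALSE)
  config <- list(manifest = do.call(rbind, manifest),
                 centers_path = centers_path, output_dir = NULL)
  attr(config, "truths") <- truths
  config
}
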