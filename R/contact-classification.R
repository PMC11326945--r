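#' Contact-classification configuration
#'
#' @param gap_nm maximum boundary-to-boundary distance (nm) between two
#'   fitted circles for a membrane point to count as a contact. The default
#'   30 nm reflects the observed apposition distance of adjacent
#'   peroxisomes.
#' @return A list of class `contact_config`.
#' @export
contact_config <- function(gap_nm = 30) {
  if (!is.numeric(gap_nm) || length(gap_nm) != 1L || gap_nm <= 0)
    stop_typed("validation_error", "gap_nm must be a single positive number")
  structure(list(gap_nm = gap_nm), class = "contact_config")
}

#' Label membrane arc samples as Between or Outside
#'
#' A sample at angle `theta` on ring `i` sits at
#' `p = center_i + r_i * (cos theta, sin theta)`. It is labeled Between
#' when its distance to the boundary of any other fitted ring in the same
#' image, `| ||p - center_j|| - r_j |`, converted to nanometres, is at most
#' `gap_nm`; otherwise it is Outside (cytosol-exposed).
#'
#' @param fit_i the ring being labeled (`ring_fit_result`).
#' @param all_fits list of all `ring_fit_result`s in the same image,
#'   including `fit_i` (matched by identical center; self is skipped).
#' @param profile_angles angles of the profile samples (radians).
#' @param config a [contact_config()].
#'
#' @return An `arc_labeling` with per-sample logical `is_between`, the gap
#'   used, and the indices of neighboring rings that contributed.
#' @export
label_arc_samples <- function(fit_i, all_fits, profile_angles,
                              config = contact_config()) {
  if (length(all_fits) < 1L)
    stop_typed("validation_error", "all_fits must contain at least one ring")
  p_row <- fit_i$center[1] + fit_i$radius_px * cos(profile_angles)
  p_col <- fit_i$center[2] + fit_i$radius_px * sin(profile_angles)
  gap_px <- config$gap_nm / fit_i$pixel_size_nm
  is_between <- rep(FALSE, length(profile_angles))
  neighbors <- integer(0)
  for (j in seq_along(all_fits)) {
    fj <- all_fits[[j]]
    if (isTRUE(all.equal(fj$center, fit_i$center)) &&
        isTRUE(all.equal(fj$radius_px, fit_i$radius_px))) next
    d <- sqrt((p_row - fj$center[1])^2 + (p_col - fj$center[2])^2)
    hit <- abs(d - fj$radius_px) <= gap_px
    if (any(hit)) neighbors <- c(neighbors, j)
    is_between <- is_between | hit
  }
  structure(list(ring_id = fit_i$ring_id, is_between = is_between,
                 gap_nm = config$gap_nm, neighbors = neighbors),
            class = "arc_labeling")
}

#' Class means of the companion channel over Between and Outside arcs
#'
#' @param profile a `membrane_profile`.
#' @param labeling an `arc_labeling` for the same ring with the same number
#'   of samples.
#'
#' @return List with `mean_between`, `mean_outside` (NA when the class is
#'   empty), `n_between`, `n_outside`.
#' @export
between_outside_means <- function(profile, labeling) {
  v <- profile$intensities_ch2
  m <- labeling$is_between
  if (length(v) != length(m))
    stop_typed("validation_error",
               "profile has %d samples but labeling has %d",
               length(v), length(m))
  nb <- sum(m); no <- sum(!m)
  list(mean_between = if (nb > 0) mean(v[m]) else NA_real_,
       mean_outside = if (no > 0) mean(v[!m]) else NA_real_,
       n_between = nb, n_outside = no)
}

#' Predominant companion-channel localisation of one cell
#'
#' Pools the per-ring Between/Outside means of a cell's rings, weighting
#' each ring's class mean by its sample count, and classifies the cell as
#' `outside` when the pooled Outside mean exceeds the pooled Between mean
#' (ratio > 1), `between` otherwise (ties conservatively count as
#' between), and `indeterminate` when either pooled class is empty (e.g. a
#' cell whose only peroxisome has no contacts).
#'
#' @param records data.frame of the cell's per-ring rows with columns
#'   `mean_between_ch2`, `mean_outside_ch2`, `n_between`, `n_outside` (and
#'   optionally `cell_id`, `condition`, `replicate`, carried through).
#'
#' @return One-row data.frame with `predominant` and
#'   `ratio_outside_over_between`.
#' @export
classify_cell <- function(records) {
  if (is.null(records) || nrow(records) < 1L)
    stop_typed("validation_error", "no records for cell")
  wb <- records$n_between; wo <- records$n_outside
  okb <- wb > 0 & !is.na(records$mean_between_ch2)
  oko <- wo > 0 & !is.na(records$mean_outside_ch2)
  pooled_between <- if (any(okb))
    sum(records$mean_between_ch2[okb] * wb[okb]) / sum(wb[okb]) else NA_real_
  pooled_outside <- if (any(oko))
    sum(records$mean_outside_ch2[oko] * wo[oko]) / sum(wo[oko]) else NA_real_
  if (is.na(pooled_between) || is.na(pooled_outside) || pooled_between == 0) {
    predominant <- "indeterminate"
    ratio <- NA_real_
  } else {
    ratio <- pooled_outside / pooled_between
    predominant <- if (ratio > 1) "outside" else "between"
  }
  out <- data.frame(
    cell_id = if ("cell_id" %in% names(records)) records$cell_id[1] else NA,
    condition = if ("condition" %in% names(records)) records$condition[1] else NA,
    replicate = if ("replicate" %in% names(records)) records$replicate[1] else NA,
    n_rings = nrow(records),
    pooled_between = pooled_between, pooled_outside = pooled_outside,
    ratio_outside_over_between = ratio, predominant = predominant,
    stringsAsFactors = FALSE)
  out
}

#' Percentage of cells with predominantly Outside localisation
#'
#' @param cells data.frame of per-cell rows (from [classify_cell()]) with a
#'   `predominant` column.
#'
#' @return List with `percentage` (`100 * outside / (outside + between)`,
#'   NA when no cell is determinate), the class counts, and the number of
#'   indeterminate cells excluded.
#' @export
outside_percentage <- function(cells) {
  if (is.null(cells) || nrow(cells) < 1L)
    stop_typed("validation_error", "no cells supplied")
  n_out <- sum(cells$predominant == "outside")
  n_btw <- sum(cells$predominant == "between")
  n_ind <- sum(cells$predominant == "indeterminate")
  pct <- if (n_out + n_btw > 0) 100 * n_out / (n_out + n_btw) else NA_real_
  if (is.na(pct))
    message("outside_percentage: all ", n_ind, " cells indeterminate")
  list(percentage = pct, n_outside = n_out, n_between = n_btw,
       n_indeterminate = n_ind)
}
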