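#' One-way (single-factor) analysis of variance
#'
#' Classical fixed-effects ANOVA, `F = MS_between / MS_within` with
#' `(k - 1, N - k)` degrees of freedom and an upper-tail p-value.
#'
#' @param groups list of two or more numeric vectors, each with at least
#'   two values.
#'
#' @return A `test_result` list: `test`, `statistic`, `df` (length 2),
#'   `p_value`, `groups` (sizes).
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop_typed("validation_error", "need at least 2 groups")
  if (any(vapply(groups, length, 1L) < 2L))
    stop_typed("validation_error", "every group needs at least 2 values")
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  if (all(vapply(groups, stats::var, 1) == 0))
    stop_typed("degenerate_error", "zero within-group variance in all groups")
  ht <- stats::oneway.test(values ~ g, var.equal = TRUE)
  structure(list(test = "one_way_anova",
                 statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = unname(ht$p.value),
                 tails = "upper",
                 groups = vapply(groups, length, 1L)),
            class = "test_result")
}

#' One-tailed paired t-test
#'
#' Tests the mean of the paired differences `d = y - x`:
#' `t = mean(d) / (sd(d) / sqrt(n))` on `n - 1` degrees of freedom, with a
#' one-sided p-value in the stated direction (`"greater"` tests d > 0).
#'
#' @param x,y paired numeric vectors of equal length `n >= 2`.
#' @param direction `"greater"` or `"less"` — the tested tail of `y - x`.
#'
#' @return A `test_result` list.
#' @export
paired_t_one_tailed <- function(x, y, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  if (length(x) != length(y))
    stop_typed("validation_error", "x and y differ in length")
  if (anyNA(x) || anyNA(y))
    stop_typed("validation_error", "paired samples contain missing values")
  if (length(x) < 2L)
    stop_typed("validation_error", "need at least 2 pairs")
  d <- y - x
  if (stats::var(d) == 0 && mean(d) != 0)
    stop_typed("degenerate_error", "paired differences have zero variance")
  if (stats::var(d) == 0 && mean(d) == 0) {
    ## all differences exactly zero: t = 0, p = 0.5 by convention
    return(structure(list(test = "paired_t_one_tailed", statistic = 0,
                          df = length(x) - 1L, p_value = 0.5,
                          tails = direction, groups = c(length(x), length(y))),
                     class = "test_result"))
  }
  ht <- stats::t.test(y, x, paired = TRUE, alternative = direction)
  structure(list(test = "paired_t_one_tailed",
                 statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = unname(ht$p.value),
                 tails = direction,
                 groups = c(length(x), length(y))),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s: stat = %.4g, df = %s, p = %.3g (%s)\n",
              x$test, x$statistic, paste(round(x$df, 2), collapse = ", "),
              x$p_value, x$tails))
  invisible(x)
}

#' Summarise per-ring and per-cell measurements by condition
#'
#' Computes per-condition (and per-replicate) means and SDs of the ring
#' metrics (circumference, companion-channel intensity, correlation R) and
#' the per-condition outside percentage; runs a one-way ANOVA across
#' conditions on each ring metric, and optionally a one-tailed paired
#' t-test on replicate-level outside percentages between two named
#' conditions.
#'
#' @param records per-ring data.frame with columns `condition`,
#'   `replicate`, `circumference_nm`, `mean_ch2`, `R`.
#' @param cells per-cell data.frame with columns `condition`, `replicate`,
#'   `predominant`.
#' @param anova_level `"ring"` (pool rings across replicates, the default)
#'   or `"replicate"` (ANOVA on replicate means).
#' @param paired_conditions optional length-2 character vector naming the
#'   conditions whose replicate-level outside percentages are compared by
#'   the paired t-test (in `x`, `y` order).
#' @param paired_direction tested tail for the paired comparison.
#'
#' @return List with data.frames `summary` (one row per condition),
#'   `replicate_summary`, `outside` (per condition x replicate) and `tests`
#'   (one row per test).
#' @export
summarize_conditions <- function(records, cells = NULL,
                                 anova_level = c("ring", "replicate"),
                                 paired_conditions = NULL,
                                 paired_direction = c("greater", "less")) {
  anova_level <- match.arg(anova_level)
  paired_direction <- match.arg(paired_direction)
  need <- c("condition", "replicate")
  if (!all(need %in% names(records)))
    stop_typed("schema_error", "records must carry condition and replicate labels")
  records <- records[order(records$condition, records$replicate), , drop = FALSE]

  metrics <- intersect(c("circumference_nm", "mean_ch2", "R"), names(records))
  agg <- function(df) {
    out <- data.frame(n_rings = nrow(df))
    for (m in metrics) {
      v <- df[[m]][!is.na(df[[m]])]
      out[[paste0("mean_", m)]] <- if (length(v)) mean(v) else NA_real_
      out[[paste0("sd_", m)]] <- if (length(v) > 1) stats::sd(v) else NA_real_
      out[[paste0("n_", m)]] <- length(v)
    }
    out
  }
  conds <- unique(records$condition)
  summary_df <- do.call(rbind, lapply(conds, function(cc) {
    cbind(data.frame(condition = cc),
          agg(records[records$condition == cc, , drop = FALSE]))
  }))
  rep_keys <- unique(records[, c("condition", "replicate")])
  replicate_summary <- do.call(rbind, lapply(seq_len(nrow(rep_keys)), function(i) {
    sel <- records$condition == rep_keys$condition[i] &
      records$replicate == rep_keys$replicate[i]
    cbind(rep_keys[i, , drop = FALSE], agg(records[sel, , drop = FALSE]))
  }))
  rownames(replicate_summary) <- NULL

  tests <- list()
  if (length(conds) >= 2L) {
    for (m in metrics) {
      grp <- if (anova_level == "ring") {
        lapply(conds, function(cc)
          stats::na.omit(records[[m]][records$condition == cc]))
      } else {
        lapply(conds, function(cc) {
          sub <- replicate_summary[replicate_summary$condition == cc, ]
          stats::na.omit(sub[[paste0("mean_", m)]])
        })
      }
      grp <- grp[vapply(grp, length, 1L) >= 2L]
      if (length(grp) >= 2L && any(vapply(grp, stats::var, 1) > 0)) {
        tr <- one_way_anova(grp)
        tests[[length(tests) + 1L]] <- data.frame(
          test = "one_way_anova", metric = m, statistic = tr$statistic,
          df1 = tr$df[1], df2 = tr$df[2], p_value = tr$p_value,
          tails = tr$tails, level = anova_level,
          groups = paste(conds, collapse = "|"), stringsAsFactors = FALSE)
      }
    }
  } else {
    message("summarize_conditions: single condition, no ANOVA run")
  }

  outside_df <- NULL
  if (!is.null(cells) && nrow(cells)) {
    keys <- unique(cells[, c("condition", "replicate")])
    outside_df <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
      sel <- cells$condition == keys$condition[i] &
        cells$replicate == keys$replicate[i]
      op <- outside_percentage(cells[sel, , drop = FALSE])
      cbind(keys[i, , drop = FALSE],
            data.frame(outside_percentage = op$percentage,
                       n_outside = op$n_outside, n_between = op$n_between,
                       n_indeterminate = op$n_indeterminate))
    }))
    rownames(outside_df) <- NULL
    if (!is.null(paired_conditions)) {
      a <- outside_df[outside_df$condition == paired_conditions[1], ]
      b <- outside_df[outside_df$condition == paired_conditions[2], ]
      a <- a[order(a$replicate), ]; b <- b[order(b$replicate), ]
      ## replicates where either condition has no determinate cell drop
      ## out of the paired comparison (their percentage is undefined)
      if (nrow(a) == nrow(b)) {
        complete <- !is.na(a$outside_percentage) & !is.na(b$outside_percentage)
        a <- a[complete, , drop = FALSE]; b <- b[complete, , drop = FALSE]
      }
      if (nrow(a) == nrow(b) && nrow(a) >= 2L) {
        tr <- paired_t_one_tailed(a$outside_percentage, b$outside_percentage,
                                  paired_direction)
        tests[[length(tests) + 1L]] <- data.frame(
          test = "paired_t_one_tailed", metric = "outside_percentage",
          statistic = tr$statistic, df1 = tr$df, df2 = NA_real_,
          p_value = tr$p_value, tails = tr$tails, level = "replicate",
          groups = paste(paired_conditions, collapse = "|"),
          stringsAsFactors = FALSE)
      }
    }
  }

  tests_df <- if (length(tests)) do.call(rbind, tests) else
    data.frame(test = character(), metric = character(),
               statistic = numeric(), df1 = numeric(), df2 = numeric(),
               p_value = numeric(), tails = character(), level = character(),
               groups = character(), stringsAsFactors = FALSE)
  list(summary = summary_df, replicate_summary = replicate_summary,
       outside = outside_df, tests = tests_df)
}
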