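# Outlier exclusion and nested group comparison.

#' Exclude observations more than k SDs from their cell mean
#'
#' Single-pass rule: within each cell (default structure x stage x group,
#' pooled over specimens), an observation is excluded when it deviates from
#' the cell mean by more than `k` cell standard deviations. Mean and SD for
#' each observation are computed leaving that observation out (the
#' jackknifed z-score): with the candidate included, a lone outlier in a
#' small cell inflates the SD enough that no point of an n-point sample can
#' ever exceed (n-1)/sqrt(n) SDs, and the rule would be vacuous at this
#' study's cell sizes. All observations are tested against the original
#' data in one pass; nothing is re-tested after removal. Set
#' `by = c(by, "specimen")` for per-specimen exclusion.
#'
#' @param df Tibble of observations.
#' @param value_col Name of the value column.
#' @param k SD multiplier; default 3.
#' @param by Cell-defining columns present in `df`.
#' @return List with tibbles `kept` and `excluded`.
#' @export
exclude_outliers <- function(df, value_col = "value", k = 3,
                             by = intersect(c("structure", "stage", "group"),
                                            names(df))) {
  stopifnot(value_col %in% names(df), length(by) > 0)
  sizes <- df |>
    dplyr::count(dplyr::across(dplyr::all_of(by)))
  if (any(sizes$n < 2)) {
    abort("Every exclusion cell needs at least 2 observations.",
          class = "ivdmech_error_insufficient_data")
  }
  loo_flag <- function(x) {
    n <- length(x)
    if (n < 3) return(rep(FALSE, n))      # LOO SD undefined
    s <- sum(x); ss <- sum(x^2)
    m_i <- (s - x) / (n - 1)
    var_i <- pmax((ss - x^2 - (n - 1) * m_i^2) / (n - 2), 0)
    abs(x - m_i) > k * sqrt(var_i)
  }
  flagged <- df |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::mutate(.out = loo_flag(.data[[value_col]])) |>
    dplyr::ungroup()
  list(kept = dplyr::select(dplyr::filter(flagged, !.data$.out), -".out"),
       excluded = dplyr::select(dplyr::filter(flagged, .data$.out), -".out"))
}

#' Compare two groups with specimen as a random factor
#'
#' Fits the nested model y = mu + group + specimen(random) + error and
#' tests the fixed group effect with containment denominator degrees of
#' freedom (number of specimens minus number of groups), so 3 + 3 specimens
#' give an F(1, 4) test. Operationally the test is one-way ANOVA on the
#' specimen means (specimens weighted equally, which for balanced data is
#' exactly the mixed-model F-test and is taken as the definition for
#' unbalanced data).
#'
#' @param df Tibble of per-indent observations.
#' @param value_col,group_col,specimen_col Column names.
#' @return Object of class `group_comparison`: `F_value`, `df1`, `df2`,
#'   `p_value`, `group_means` (specimen-level mean +/- SD per group),
#'   `specimen_means`, `n_obs`. Supports [tidy()], [glance()],
#'   [autoplot()].
#' @export
compare_groups <- function(df, value_col = "value", group_col = "group",
                           specimen_col = "specimen") {
  stopifnot(all(c(value_col, group_col, specimen_col) %in% names(df)))
  df <- df[is.finite(df[[value_col]]), , drop = FALSE]

  spec_means <- df |>
    dplyr::group_by(.data[[group_col]], .data[[specimen_col]]) |>
    dplyr::summarise(mean_value = mean(.data[[value_col]]),
                     n_indents = dplyr::n(), .groups = "drop") |>
    dplyr::rename(group = 1, specimen = 2)

  counts <- dplyr::count(spec_means, .data$group)
  if (any(counts$n < 2)) {
    abort("Each group needs at least 2 specimens after exclusion.",
          class = "ivdmech_error_insufficient_replication")
  }

  n_groups <- nrow(counts)
  n_specimens <- nrow(spec_means)
  fit <- lm(mean_value ~ group, data = spec_means)
  an <- anova(fit)
  F_value <- an$`F value`[1]
  df1 <- an$Df[1]
  df2 <- an$Df[2]
  p_value <- an$`Pr(>F)`[1]
  stopifnot(df1 == n_groups - 1, df2 == n_specimens - n_groups)

  group_means <- spec_means |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n_specimens = dplyr::n(),
                     mean = mean(.data$mean_value),
                     sd = sd(.data$mean_value), .groups = "drop")

  structure(
    list(F_value = F_value, df1 = df1, df2 = df2, p_value = p_value,
         group_means = group_means, specimen_means = spec_means,
         n_obs = nrow(df), value_col = value_col),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison: F(%d,%d) = %.3g, p = %.3g (%s)>\n",
              x$df1, x$df2, x$F_value, x$p_value, x$value_col))
  print(x$group_means)
  invisible(x)
}

#' Group-comparison table over structures, levels and metrics
#'
#' Convenience wrapper producing one comparison per structure x level x
#' stage cell and metric (instantaneous modulus and elastic fraction),
#' after three-SD outlier exclusion, shaped like a published summary table.
#'
#' @param observations Per-indent tibble with columns `group`, `specimen`,
#'   `structure`, `level`, `stage` and the metric columns.
#' @param metrics Named character vector of metric columns.
#' @param k Outlier-exclusion SD multiplier.
#' @return Tibble with one row per cell x metric x group carrying the
#'   specimen-level mean and SD plus the shared F, df and p of the cell.
#' @export
comparison_table <- function(observations,
                             metrics = c(E_ins_kPa = "E_ins_kPa",
                                         f = "f"),
                             k = 3) {
  cells <- observations |>
    dplyr::distinct(.data$structure, .data$level, .data$stage)
  purrr::pmap(cells, function(structure, level, stage) {
    cell <- observations[observations$structure == structure &
                           observations$level %in% level &
                           observations$stage %in% stage, ]
    purrr::imap(metrics, function(col, label) {
      excl <- exclude_outliers(cell, value_col = col, k = k,
                               by = "group")
      cmp <- compare_groups(excl$kept, value_col = col)
      cmp$group_means |>
        dplyr::mutate(structure = structure, level = level, stage = stage,
                      metric = label, F_value = cmp$F_value,
                      df1 = cmp$df1, df2 = cmp$df2, p_value = cmp$p_value,
                      n_excluded = nrow(excl$excluded), .before = 1)
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
}
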