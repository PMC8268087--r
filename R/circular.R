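# Axial circular statistics (angles modulo 180 deg, doubled-angle method).

#' Axial circular mean
#'
#' Angles are doubled onto the full circle, the resultant direction is
#' taken, and the result is halved back, giving the mean orientation in
#' `[0, 180)`. E.g. the axial mean of 10 and 170 deg is 0 deg, not 90.
#'
#' @param theta_deg Axial angles in degrees.
#' @return The axial mean in degrees in `[0, 180)`.
#' @export
axial_mean_deg <- function(theta_deg) {
  phi <- 2 * theta_deg * pi / 180
  (atan2(mean(sin(phi)), mean(cos(phi))) * 180 / pi / 2) %% 180
}

# signed axial deviation in (-90, 90]
axial_deviation_deg <- function(theta_deg, from_deg) {
  ((theta_deg - from_deg + 90) %% 180) - 90
}

#' Summarize a set of axial angles
#'
#' Computes the axial circular mean (doubled-angle method), the circular
#' standard deviation `0.5 * sqrt(-2 ln Rbar)` (in degrees, where `Rbar` is
#' the mean resultant length on doubled angles), a histogram over
#' `[0, 180)`, and a predominance flag (`FALSE` when `Rbar` falls below
#' `predominant_min_r`, marking regions with no predominant orientation).
#'
#' @param theta_deg Non-empty vector of axial angles (degrees).
#' @param n_bins Number of histogram bins over `[0, 180)`; default 36
#'   (5-degree bins).
#' @param predominant_min_r Threshold on the mean resultant length.
#' @return Object of class `region_orientation_summary` with fields
#'   `circular_mean_deg`, `circular_dispersion_deg`, `resultant_length`,
#'   `n_pixels`, `predominant` and a `histogram` tibble (`bin_left_deg`,
#'   `bin_right_deg`, `count`). Supports [tidy()] (histogram) and
#'   [glance()] (one-row summary).
#' @examples
#' circular_summary(c(10, 170))$circular_mean_deg # 0, not 90
#' @export
circular_summary <- function(theta_deg, n_bins = 36,
                             predominant_min_r = 0.1) {
  theta_deg <- theta_deg[!is.na(theta_deg)]
  if (!length(theta_deg)) {
    abort("No angles to summarize.", class = "ivdmech_error_no_data")
  }
  theta_deg <- theta_deg %% 180
  phi <- 2 * theta_deg * pi / 180
  C <- mean(cos(phi)); S <- mean(sin(phi))
  rbar <- min(sqrt(C^2 + S^2), 1)
  mean_deg <- (atan2(S, C) * 180 / pi / 2) %% 180
  disp_deg <- if (rbar > 0) 0.5 * sqrt(-2 * log(rbar)) * 180 / pi else Inf

  breaks <- seq(0, 180, length.out = n_bins + 1)
  counts <- tabulate(findInterval(theta_deg, breaks,
                                  rightmost.closed = FALSE), nbins = n_bins)
  structure(
    list(circular_mean_deg = mean_deg, circular_dispersion_deg = disp_deg,
         resultant_length = rbar, n_pixels = length(theta_deg),
         predominant = rbar >= predominant_min_r,
         histogram = tibble(bin_left_deg = breaks[-length(breaks)],
                            bin_right_deg = breaks[-1], count = counts)),
    class = "region_orientation_summary"
  )
}

#' @export
print.region_orientation_summary <- function(x, ...) {
  cat(sprintf(
    "<orientation summary: mean %.1f deg, dispersion %.1f deg, n = %d%s>\n",
    x$circular_mean_deg, x$circular_dispersion_deg, x$n_pixels,
    if (!x$predominant) ", no predominant orientation" else ""))
  invisible(x)
}

#' Across-sample orientation table per region and group
#'
#' Aggregates per-sample circular means: the across-sample mean is the
#' axial circular mean of the per-sample means, and the across-sample SD is
#' the root-mean-square axial deviation from that mean (degrees), so that
#' samples straddling the 0/180 wrap (e.g. 5, 175, 0 deg) summarize
#' correctly.
#'
#' @param df Tibble with one row per sample x region containing the
#'   per-sample circular means.
#' @param mean_col Name of the per-sample mean column.
#' @param by Grouping columns (e.g. stage, group, region/quadrant).
#' @return Tibble with the grouping columns plus `n_samples`, `mean_deg`,
#'   `sd_deg`.
#' @export
group_orientation_table <- function(df, mean_col = "circular_mean_deg",
                                    by = intersect(c("stage", "group",
                                                     "quadrant", "region"),
                                                   names(df))) {
  stopifnot(mean_col %in% names(df), length(by) > 0)
  df |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      n_samples = dplyr::n(),
      mean_deg = axial_mean_deg(.data[[mean_col]]),
      sd_deg = sqrt(mean(
        axial_deviation_deg(.data[[mean_col]],
                            axial_mean_deg(.data[[mean_col]]))^2)),
      .groups = "drop"
    )
}
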