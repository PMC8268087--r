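# ggplot2 autoplot methods.

#' @describeIn fit_sls Force-time curve with the fitted model overlaid.
#' @param object The fitted object.
#' @export
autoplot.sls_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$time_s)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$force_uN),
                        size = 0.6, alpha = 0.5) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted_uN),
                       colour = "firebrick", linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = object$t_ramp_end_s,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::labs(
      x = "time since contact (s)", y = "force (uN)",
      title = sprintf("SLS fit: E_ins %.3g kPa, E_eq %.3g kPa, f %.2f",
                      object$E_ins_kPa, object$E_eq_kPa, object$f)) +
    ggplot2::theme_minimal()
}

#' @describeIn compare_groups Specimen means by group with the F-test in
#'   the caption.
#' @param object The fitted object.
#' @export
autoplot.group_comparison <- function(object, ...) {
  ggplot2::ggplot(object$specimen_means,
                  ggplot2::aes(x = .data$group, y = .data$mean_value)) +
    ggplot2::geom_point(position = ggplot2::position_jitter(width = 0.08),
                        size = 2) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          linewidth = 0.3) +
    ggplot2::labs(
      x = NULL, y = sprintf("specimen mean (%s)", object$value_col),
      caption = sprintf("F(%d,%d) = %.3g, p = %.3g", object$df1, object$df2,
                        object$F_value, object$p_value)) +
    ggplot2::theme_minimal()
}

#' @describeIn circular_summary Polar histogram of the axial distribution
#'   (each orientation shown at theta and theta + 180).
#' @param object The summary object.
#' @export
autoplot.region_orientation_summary <- function(object, ...) {
  h <- object$histogram
  mid <- (h$bin_left_deg + h$bin_right_deg) / 2
  df <- tibble(angle = c(mid, mid + 180), count = rep(h$count, 2))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$angle, y = .data$count)) +
    ggplot2::geom_col(width = diff(mid[1:2]), fill = "steelblue") +
    ggplot2::coord_polar(start = -pi / 2, direction = -1) +
    ggplot2::scale_x_continuous(limits = c(0, 360),
                                breaks = seq(0, 330, 30)) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("mean %.1f deg (dispersion %.1f deg)",
                                  object$circular_mean_deg,
                                  object$circular_dispersion_deg)) +
    ggplot2::theme_minimal()
}

#' @describeIn orientation_field Orientation map (hue = angle, alpha =
#'   coherency, masked pixels blank).
#' @param object The field object.
#' @export
autoplot.orientation_field <- function(object, ...) {
  df <- tidy.orientation_field(object)
  df <- df[df$valid, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = -.data$row,
                                   fill = .data$theta_deg,
                                   alpha = .data$coherency)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradientn(
      colours = c("#e41a1c", "#ff7f00", "#ffff33", "#4daf4a", "#377eb8",
                  "#984ea3", "#e41a1c"),
      limits = c(0, 180), name = "angle (deg)") +
    ggplot2::scale_alpha_continuous(range = c(0.2, 1), guide = "none") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_void()
}
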