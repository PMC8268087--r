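# broom-style tidiers for fitted objects.

#' @describeIn fit_sls Tidy the fitted SLS parameters (one row per
#'   parameter: E0, E1, tau1).
#' @param x An `sls_fit`.
#' @param ... Unused.
#' @export
tidy.sls_fit <- function(x, ...) {
  tibble(term = c("E0_kPa", "E1_kPa", "tau1_s"),
         estimate = c(x$params$E0_kPa, x$params$E1_kPa, x$params$tau1_s))
}

#' @describeIn fit_sls One-row fit summary (derived moduli, elastic
#'   fraction, diagnostics).
#' @export
glance.sls_fit <- function(x, ...) {
  tibble(E_ins_kPa = x$E_ins_kPa, E_eq_kPa = x$E_eq_kPa, f = x$f,
         tau1_s = x$params$tau1_s, rmse_uN = x$rmse_uN,
         r_squared = x$r_squared, n_points = x$n_points,
         converged = x$converged,
         flags = paste(x$flags, collapse = ";"))
}

#' @describeIn compare_groups Specimen-level group means, one row per group.
#' @param x A `group_comparison`.
#' @param ... Unused.
#' @export
tidy.group_comparison <- function(x, ...) x$group_means

#' @describeIn compare_groups One-row test summary (F, df pair, p).
#' @export
glance.group_comparison <- function(x, ...) {
  tibble(F_value = x$F_value, df1 = x$df1, df2 = x$df2,
         p_value = x$p_value, n_obs = x$n_obs,
         n_specimens = nrow(x$specimen_means))
}

#' @describeIn circular_summary Histogram of the summarized angles.
#' @param x A `region_orientation_summary`.
#' @param ... Unused.
#' @export
tidy.region_orientation_summary <- function(x, ...) x$histogram

#' @describeIn circular_summary One-row circular summary.
#' @export
glance.region_orientation_summary <- function(x, ...) {
  tibble(n_pixels = x$n_pixels, circular_mean_deg = x$circular_mean_deg,
         circular_dispersion_deg = x$circular_dispersion_deg,
         resultant_length = x$resultant_length,
         predominant = x$predominant)
}

#' @describeIn orientation_field Long-format pixel table (row, col, angle,
#'   coherency, validity).
#' @param x An `orientation_field`.
#' @param ... Unused.
#' @export
tidy.orientation_field <- function(x, ...) {
  nr <- nrow(x$theta_deg); nc <- ncol(x$theta_deg)
  tibble(row = rep(seq_len(nr), times = nc),
         col = rep(seq_len(nc), each = nr),
         theta_deg = as.vector(x$theta_deg),
         coherency = as.vector(x$coherency),
         valid = as.vector(x$valid_mask))
}
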