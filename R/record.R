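#' Construct an indentation record
#'
#' An indentation record is a tibble with columns `time_s`,
#' `displacement_um` and `force_uN`, carrying the tip radius, Poisson's
#' ratio and specimen metadata as attributes. All downstream functions
#' (contact detection, fitting, validity checks) accept this object.
#'
#' @param time_s Strictly increasing time stamps (s).
#' @param displacement_um Commanded displacement (um); negative values
#'   denote the pre-contact approach.
#' @param force_uN Measured force (uN).
#' @param tip_radius_um Spherical tip radius (um); default 42.
#' @param poisson_ratio Poisson's ratio; 0.5 (incompressible) by default.
#' @param spring_constant_N_m Cantilever spring constant, carried as
#'   metadata only (commanded displacement is treated as indentation depth).
#' @param meta Named list of specimen metadata (group, specimen, structure,
#'   level, stage).
#' @param ground_truth Optional list of generator provenance (true
#'   parameters, contact index); attached by [generate_indent_curve()].
#'
#' @return A tibble of class `indent_record`.
#' @export
indent_record <- function(time_s, displacement_um, force_uN,
                          tip_radius_um = 42, poisson_ratio = 0.5,
                          spring_constant_N_m = 0.48,
                          meta = list(), ground_truth = NULL) {
  n <- length(time_s)
  if (length(displacement_um) != n || length(force_uN) != n) {
    abort("time, displacement and force series must have equal length.",
          class = "ivdmech_error_data")
  }
  if (n >= 2 && any(diff(time_s) <= 0)) {
    abort("time_s must be strictly increasing.", class = "ivdmech_error_data")
  }
  if (!is.finite(tip_radius_um) || tip_radius_um <= 0) {
    abort("tip_radius_um must be > 0.", class = "ivdmech_error_data")
  }
  if (poisson_ratio < 0 || poisson_ratio > 0.5) {
    abort("poisson_ratio must lie in [0, 0.5].", class = "ivdmech_error_data")
  }
  out <- tibble(time_s = as.numeric(time_s),
                displacement_um = as.numeric(displacement_um),
                force_uN = as.numeric(force_uN))
  structure(out,
            tip_radius_um = tip_radius_um,
            poisson_ratio = poisson_ratio,
            spring_constant_N_m = spring_constant_N_m,
            meta = meta,
            ground_truth = ground_truth,
            class = c("indent_record", class(out)))
}

record_attr <- function(record, what) attr(record, what, exact = TRUE)

#' @export
print.indent_record <- function(x, ...) {
  meta <- record_attr(x, "meta")
  cat(sprintf("<indent_record: %d samples, R = %g um, nu = %g>\n",
              nrow(x), record_attr(x, "tip_radius_um"),
              record_attr(x, "poisson_ratio")))
  if (length(meta)) {
    cat("  ", paste(names(meta), unlist(meta), sep = "=", collapse = " "),
        "\n", sep = "")
  }
  NextMethod()
}

rolling_mean <- function(x, window) {
  if (window <= 1) return(x)
  sm <- stats::filter(x, rep(1 / window, window), sides = 2)
  sm <- as.numeric(sm)
  sm[is.na(sm)] <- x[is.na(sm)]
  sm
}

#' Detect the contact point of an indentation curve
#'
#' The baseline (pre-contact) force level and drift are estimated from the
#' pre-rise region by a linear fit. Contact is the first sample where the
#' smoothed force exceeds the extrapolated baseline by
#' `delta = max(abs_threshold, rel_threshold * (P_max - baseline))` and
#' stays above it for `persistence` consecutive samples; the detected index
#' is then backtracked along the raw residual to the start of the rise.
#' The default absolute threshold of 0.003 uN, with a relative alternative
#' of 0.5 % of the maximum force, reflects typical noise floors of
#' cantilever-based nanoindenters on soft hydrated tissue.
#'
#' @param record An [indent_record()] containing a pre-contact baseline.
#' @param abs_threshold_uN Absolute force-rise threshold (uN).
#' @param rel_threshold Relative threshold as a fraction of the
#'   baseline-corrected maximum force.
#' @param smooth_window Width (samples) of the centred moving-average
#'   smoother used for detection.
#' @param persistence Number of consecutive samples the force must remain
#'   above threshold.
#'
#' @return An object of class `contact_point`: list with `index` (1-based
#'   sample index of contact), `t0_s`, `h0_um`, `P0_uN` (offsets that zero
#'   the curve at contact) and `threshold_used_uN`.
#' @export
detect_contact <- function(record, abs_threshold_uN = 0.003,
                           rel_threshold = 0.005, smooth_window = 5,
                           persistence = 5) {
  P <- record$force_uN
  t <- record$time_s
  n <- length(P)
  if (n < smooth_window + persistence + 5) {
    abort("Record too short for contact detection.",
          class = "ivdmech_error_insufficient_data")
  }
  Ps <- rolling_mean(P, smooth_window)

  ## pre-rise region: the smoothed force first reaches 20 % of its
  ## excursion at `coarse`; only a 60 % prefix of the samples before that
  ## is used for the baseline fit, keeping the rise onset out of it
  lo <- quantile(Ps, 0.01, names = FALSE)
  coarse <- which(Ps > lo + 0.2 * (max(Ps) - lo))[1]
  if (is.na(coarse)) coarse <- n
  base_end <- max(min(10, n), floor(0.6 * (coarse - smooth_window)))
  base_idx <- seq_len(min(base_end, n))
  base_fit <- lm(y ~ x, data = data.frame(x = t[base_idx], y = P[base_idx]))
  baseline <- as.numeric(coef(base_fit)[1] + coef(base_fit)[2] * t)
  base_level <- mean(baseline[base_idx])

  delta <- max(abs_threshold_uN, rel_threshold * (max(P) - base_level))
  ## absolute gate: a record whose force never rises `delta` above the
  ## baseline level has no contact (extrapolating the baseline trend over
  ## a featureless record would otherwise manufacture spurious rises)
  if (max(Ps) - base_level <= delta) {
    abort(sprintf("Force never exceeds contact threshold (%.4g uN).", delta),
          class = "ivdmech_error_no_contact")
  }
  r_smooth <- Ps - baseline
  r_raw <- P - baseline

  ## a record that opens significantly above the baseline has no visible
  ## pre-contact segment; the noise scale comes from successive differences
  ## so that a structured (non-flat) opening cannot hide behind its own
  ## inflated residual spread
  noise_sd <- sd(diff(P[base_idx])) / sqrt(2)
  if (r_smooth[1] > max(delta, 3 * noise_sd)) {
    abort("Curve starts above the contact threshold; no baseline visible.",
          class = "ivdmech_error_ambiguous_contact")
  }

  above <- r_smooth > delta
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  ## the contact rise is the exceedance run connected to the force peak;
  ## short noise excursions in the baseline are disconnected from it
  peak <- which.max(r_smooth)
  run_of_peak <- which(runs$values & starts <= peak & ends >= peak)
  if (!length(run_of_peak) ||
      runs$lengths[run_of_peak] < persistence) {
    abort(sprintf("Force never exceeds contact threshold (%.4g uN).", delta),
          class = "ivdmech_error_no_contact")
  }
  j <- starts[run_of_peak]
  ## backtrack along the raw residual to the beginning of the rise
  i0 <- j
  while (i0 > 1 && r_raw[i0 - 1] > 0) i0 <- i0 - 1L
  if (j == 1L || i0 == 1L) {
    abort("Curve starts above the contact threshold; no baseline visible.",
          class = "ivdmech_error_ambiguous_contact")
  }

  structure(
    list(index = i0, t0_s = t[i0], h0_um = record$displacement_um[i0],
         P0_uN = P[i0], threshold_used_uN = delta,
         baseline_intercept_uN = as.numeric(coef(base_fit)[1]),
         baseline_slope_uN_s = as.numeric(coef(base_fit)[2])),
    class = "contact_point"
  )
}

#' @export
print.contact_point <- function(x, ...) {
  cat(sprintf(
    "<contact_point: index %d, t0 = %.4g s, P0 = %.4g uN, threshold %.4g uN>\n",
    x$index, x$t0_s, x$P0_uN, x$threshold_used_uN))
  invisible(x)
}
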