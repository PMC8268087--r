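#' Fit the ramp-hold SLS model to an indentation record
#'
#' Bounded nonlinear least squares of [forward_ramp_hold()] against the
#' measured force over the loading ramp and hold only (the unload segment
#' is excluded). The ramp speed and the ramp/hold boundaries are read off
#' the displacement command (ramp end at 99 % of maximum depth, ties to the
#' earlier sample); the baseline force trend estimated during contact
#' detection is subtracted. Because sample-resolution contact detection
#' leaves a systematic fraction-of-a-sample offset that biases the moduli,
#' the contact time is refined as a fourth bounded parameter (within +/- 20
#' samples of the detected index) jointly with `E0 >= 0`, `E1 >= 0` and
#' `tau1` in `[dt, 10 * t_hold]`. Starting values come from the hold
#' plateau (E0), the force at ramp end (E0 + E1) and a log-linear fit of
#' the hold decay (tau1); a small multi-start grid over tau1 is the
#' fallback on non-convergence.
#'
#' @param record An [indent_record()].
#' @param contact A [detect_contact()] result, or `NULL` to detect it here.
#'   Pass `contact = contact_at(record, 1)` to force contact at the first
#'   sample of a curve with no baseline.
#' @param segments `"ramp+hold"` (default) or `"hold"` for hold-only fits
#'   (contact time is then pinned at the detected sample).
#'
#' @return An object of class `sls_fit` with elements `params`
#'   ([sls_params()]), `E_ins_kPa`, `E_eq_kPa`, `f`, `rmse_uN`,
#'   `r_squared`, `contact_time_s`, `t_ramp_end_s`, `t_hold_end_s`
#'   (relative to contact), `converged`, `flags`, `n_points`, `meta` and a
#'   `data` tibble (time since contact, measured and fitted force).
#'   Supports [tidy()], [glance()] and [autoplot()].
#' @export
fit_sls <- function(record, contact = NULL,
                    segments = c("ramp+hold", "hold")) {
  segments <- match.arg(segments)
  if (is.null(contact)) contact <- detect_contact(record)
  stopifnot(inherits(contact, "contact_point"))

  t_all <- record$time_s
  h_all <- record$displacement_um
  b0 <- contact$baseline_intercept_uN %||% contact$P0_uN
  b1 <- contact$baseline_slope_uN_s %||% 0
  P_all <- record$force_uN - (b0 + b1 * t_all)
  ci <- contact$index
  n <- length(t_all)
  dt <- min(diff(t_all))

  ## geometry of the displacement command
  h0 <- h_all[ci]
  h_plateau <- max(h_all)
  depth_span <- h_plateau - h0
  if (depth_span <= 0) {
    abort("No indentation past the contact point.",
          class = "ivdmech_error_data")
  }
  plateau_idx <- which(h_all >= h_plateau - 0.01 * depth_span)
  plateau_idx <- plateau_idx[plateau_idx >= ci]
  ramp_first <- plateau_idx[1]
  hold_end_i <- max(plateau_idx)
  if (length(ci:hold_end_i) < 20) {
    abort("Fewer than 20 post-contact samples.",
          class = "ivdmech_error_insufficient_data")
  }
  mid <- which(h_all > h0 + 0.2 * depth_span &
                 h_all < h0 + 0.8 * depth_span)
  mid <- mid[mid >= ci & mid < ramp_first]
  if (length(mid) < 3) {
    abort("Could not identify the loading ramp from the displacement.",
          class = "ivdmech_error_data")
  }
  ramp_line <- coef(lm(h_all[mid] ~ t_all[mid]))
  v <- as.numeric(ramp_line[2])
  if (!is.finite(v) || v <= 0) {
    abort("Non-positive ramp speed in the displacement command.",
          class = "ivdmech_error_data")
  }
  ## time at which the command line reaches the plateau (independent of t_c)
  t_R_abs <- (h_plateau - as.numeric(ramp_line[1])) / v
  t_hold_end_abs <- t_all[hold_end_i]
  if (t_hold_end_abs <= t_R_abs) {
    abort("Could not identify ramp and hold segments from the displacement.",
          class = "ivdmech_error_data")
  }

  refine_tc <- segments == "ramp+hold"
  i_start <- if (refine_tc) max(1L, ci - 20L) else ramp_first
  fit_i <- i_start:hold_end_i
  tf <- t_all[fit_i]
  Pf <- P_all[fit_i]

  R <- record_attr(record, "tip_radius_um")
  nu <- record_attr(record, "poisson_ratio")
  K <- hertz_prefactor(R, nu)
  tc0 <- contact$t0_s
  tc_lo <- max(tf[1], tc0 - 20 * dt)
  tc_hi <- min(tc0 + 20 * dt, t_R_abs - 2 * dt)
  t_hold_nom <- t_hold_end_abs - t_R_abs

  model_fn <- function(E0, E1, tau1, tc) {
    depth_max <- v * (t_R_abs - tc)
    prof <- indent_profile(v_load_um_s = v, h_max_um = depth_max,
                           t_hold_s = t_hold_end_abs - t_R_abs + dt,
                           v_unload_um_s = v)
    tr <- pmax(tf - tc, 0)
    forward_ramp_hold(pmin(tr, t_R_abs - tc + t_hold_nom), prof,
                      sls_params(E0, E1, tau1), R, nu)
  }

  ## initial values from the data
  hmax0 <- v * (t_R_abs - tc0)
  plateau <- mean(Pf[tf >= t_R_abs + 0.9 * t_hold_nom])
  E0_init <- max(plateau / (K * hmax0^1.5), 1e-3)
  Eins_init <- max(P_all[ramp_first] / (K * hmax0^1.5), E0_init * 1.01)
  E1_init <- max(Eins_init - E0_init, 1e-3)
  lower <- c(0, 0, dt)
  upper <- c(Inf, Inf, 10 * t_hold_nom)
  tau_init <- {
    hi <- tf > t_R_abs & tf < t_R_abs + 0.8 * t_hold_nom
    dec <- Pf[hi] - plateau
    pos <- dec > max(dec, 0) * 1e-3
    if (sum(pos) >= 5) {
      sl <- coef(lm(log(dec[pos]) ~ tf[hi][pos]))[2]
      if (is.finite(sl) && sl < 0) min(max(-1 / sl, dt * 2), upper[3]) else 1
    } else 1
  }

  if (refine_tc) {
    lower <- c(lower, tc_lo)
    upper <- c(upper, tc_hi)
  }
  resid_fn <- function(p) {
    tc <- if (refine_tc) p[4] else tc0
    model_fn(p[1], p[2], p[3], tc) - Pf
  }
  run_fit <- function(start) {
    tryCatch(
      minpack.lm::nls.lm(start, lower = lower, upper = upper, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL
    )
  }

  start0 <- c(E0_init, E1_init, tau_init)
  if (refine_tc) start0 <- c(start0, min(max(tc0, tc_lo), tc_hi))
  best <- run_fit(start0)
  converged <- !is.null(best) && best$info %in% 1:4
  if (!converged) {
    ## multi-start fallback over relaxation times
    for (tau0 in c(0.2, 1, 2, 5, t_hold_nom)) {
      st <- start0
      st[3] <- min(max(tau0, lower[3]), upper[3])
      cand <- run_fit(st)
      if (!is.null(cand) &&
          (is.null(best) || cand$deviance < best$deviance)) best <- cand
    }
    converged <- !is.null(best) && best$info %in% 1:4
  }
  if (is.null(best)) {
    abort("SLS fit failed to run.", class = "ivdmech_error_fit")
  }

  p <- best$par
  tc_hat <- if (refine_tc) p[4] else tc0
  params <- sls_params(p[1], p[2], p[3])
  mod <- derived_moduli(params)
  fitted <- resid_fn(p) + Pf
  ss_res <- sum((Pf - fitted)^2)
  ss_tot <- sum((Pf - mean(Pf))^2)

  flags <- character()
  if (p[3] >= upper[3] * 0.999 || p[3] <= lower[3] * 1.001) {
    flags <- c(flags, "tau_at_bound")
  }
  if (mod$f < 1e-6 || mod$f > 1 - 1e-6) flags <- c(flags, "f_at_bound")

  structure(
    list(params = params,
         E_ins_kPa = mod$E_ins_kPa, E_eq_kPa = mod$E_eq_kPa, f = mod$f,
         rmse_uN = sqrt(ss_res / length(Pf)),
         r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
         contact_time_s = tc_hat,
         t_ramp_end_s = t_R_abs - tc_hat,
         t_hold_end_s = t_hold_end_abs - tc_hat,
         converged = converged, flags = flags, n_points = length(Pf),
         segments = segments,
         meta = record_attr(record, "meta"),
         data = tibble(time_s = tf - tc_hat, force_uN = Pf,
                       fitted_uN = fitted)),
    class = "sls_fit"
  )
}

#' Force a contact point at a given sample
#'
#' Helper for curves with no pre-contact baseline (e.g. noise-free
#' synthetic records starting exactly at contact).
#'
#' @param record An [indent_record()].
#' @param index 1-based sample index to treat as contact.
#' @return A `contact_point`.
#' @export
contact_at <- function(record, index = 1L) {
  stopifnot(index >= 1, index <= nrow(record))
  structure(
    list(index = as.integer(index), t0_s = record$time_s[index],
         h0_um = record$displacement_um[index],
         P0_uN = record$force_uN[index], threshold_used_uN = NA_real_),
    class = "contact_point"
  )
}

#' @export
print.sls_fit <- function(x, ...) {
  cat(sprintf(
    "<sls_fit: E_ins = %.3g kPa, E_eq = %.3g kPa, f = %.3f, tau1 = %.3g s>\n",
    x$E_ins_kPa, x$E_eq_kPa, x$f, x$params$tau1_s))
  cat(sprintf("  rmse %.3g uN, R^2 %.4f, %d points, converged: %s%s\n",
              x$rmse_uN, x$r_squared, x$n_points, x$converged,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
              else ""))
  invisible(x)
}

#' Indentation measurement validity checks
#'
#' Representative contact strain uses the Tabor convention 0.2 a / R with
#' contact radius a = sqrt(R h_max); the substrate criterion is the ratio
#' of maximum depth to section thickness. Defaults flag measurements with
#' strain of 5 % or more, or a depth exceeding 10 % of the thickness.
#'
#' @param h_max_um Maximum indentation depth (um).
#' @param tip_radius_um Tip radius (um).
#' @param section_thickness_um Section thickness (um).
#' @param strain_limit,depth_ratio_limit Thresholds for the two flags.
#' @return One-row tibble: `representative_strain`, `depth_to_thickness`,
#'   `strain_ok`, `substrate_ok`.
#' @examples
#' check_validity(2, 42, 25)
#' @export
check_validity <- function(h_max_um, tip_radius_um, section_thickness_um,
                           strain_limit = 0.05, depth_ratio_limit = 0.10) {
  stopifnot(h_max_um > 0, tip_radius_um > 0, section_thickness_um > 0)
  a <- sqrt(tip_radius_um * h_max_um)
  strain <- 0.2 * a / tip_radius_um
  ratio <- h_max_um / section_thickness_um
  tibble(representative_strain = strain, depth_to_thickness = ratio,
         strain_ok = strain < strain_limit,
         substrate_ok = ratio < depth_ratio_limit)
}
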