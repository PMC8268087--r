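# Synthetic indentation data: single curves and hierarchical cohorts.

#' Specification of a synthetic indentation curve
#'
#' @param params True [sls_params()] of the simulated material.
#' @param profile Displacement command, an [indent_profile()].
#' @param tip_radius_um Tip radius (um); default 42.
#' @param poisson_ratio Poisson's ratio; default 0.5 (incompressible).
#' @param baseline_duration_s Pre-contact approach duration (s).
#' @param noise_sd_uN SD of additive i.i.d. Gaussian force noise (uN).
#' @param drift_rate_uN_s Linear baseline force drift (uN/s).
#' @param sample_rate_hz Sampling rate (Hz); default 100.
#' @param seed Optional RNG seed for reproducible noise.
#' @param meta Specimen metadata list passed to the record.
#' @return An object of class `synthetic_indent_spec`.
#' @export
synthetic_indent_spec <- function(params, profile = indent_profile(),
                                  tip_radius_um = 42, poisson_ratio = 0.5,
                                  baseline_duration_s = 1, noise_sd_uN = 0,
                                  drift_rate_uN_s = 0, sample_rate_hz = 100,
                                  seed = NULL, meta = list()) {
  stopifnot(inherits(params, "sls_params"), inherits(profile, "indent_profile"))
  if (!is.finite(sample_rate_hz) || sample_rate_hz <= 0) {
    abort("sample_rate_hz must be > 0.", class = "ivdmech_error_invalid_spec")
  }
  if (noise_sd_uN < 0 || baseline_duration_s < 0) {
    abort("noise_sd_uN and baseline_duration_s must be >= 0.",
          class = "ivdmech_error_invalid_spec")
  }
  structure(
    list(params = params, profile = profile, tip_radius_um = tip_radius_um,
         poisson_ratio = poisson_ratio,
         baseline_duration_s = baseline_duration_s,
         noise_sd_uN = noise_sd_uN, drift_rate_uN_s = drift_rate_uN_s,
         sample_rate_hz = sample_rate_hz, seed = seed, meta = meta),
    class = "synthetic_indent_spec"
  )
}

#' Generate a synthetic ramp-hold indentation record
#'
#' Forward-simulates the trapezoidal displacement command (approach at the
#' loading speed, ramp, hold, unload) and the corresponding force: zero
#' before contact, the hereditary-integral SLS response over ramp and hold,
#' and a linear taper to zero over the unload (outside the model's domain,
#' plumbing only). Linear drift and Gaussian noise are added on top. The
#' true contact index and parameters are attached as ground-truth
#' provenance.
#'
#' @param spec A [synthetic_indent_spec()].
#' @return An [indent_record()] whose `ground_truth` attribute carries
#'   `params`, `profile`, `contact_index` and the generating spec.
#' @examples
#' rec <- generate_indent_curve(
#'   synthetic_indent_spec(sls_params(18, 6, 2), noise_sd_uN = 0.002, seed = 1))
#' @export
generate_indent_curve <- function(spec) {
  stopifnot(inherits(spec, "synthetic_indent_spec"))
  pr <- spec$profile
  t_unload <- pr$h_max_um / pr$v_unload_um_s
  t_total <- spec$baseline_duration_s + pr$t_ramp_s + pr$t_hold_s + t_unload
  t <- seq(0, t_total, by = 1 / spec$sample_rate_hz)
  h <- command_displacement(t, pr, spec$baseline_duration_s)

  tc <- t - spec$baseline_duration_s
  model_dom <- tc >= 0 & tc <= pr$t_ramp_s + pr$t_hold_s
  P <- numeric(length(t))
  P[model_dom] <- forward_ramp_hold(tc[model_dom], pr, spec$params,
                                    spec$tip_radius_um, spec$poisson_ratio)
  un <- tc > pr$t_ramp_s + pr$t_hold_s
  if (any(un)) {
    P_he <- forward_ramp_hold(pr$t_ramp_s + pr$t_hold_s, pr, spec$params,
                              spec$tip_radius_um, spec$poisson_ratio)
    frac <- (tc[un] - pr$t_ramp_s - pr$t_hold_s) / t_unload
    P[un] <- P_he * pmax(1 - frac, 0)
  }

  add_noise <- function() {
    P + spec$drift_rate_uN_s * t +
      if (spec$noise_sd_uN > 0) rnorm(length(t), 0, spec$noise_sd_uN) else 0
  }
  P <- if (!is.null(spec$seed)) withr::with_seed(spec$seed, add_noise())
       else add_noise()

  contact_index <- which(tc >= -1e-12)[1]
  indent_record(
    t, h, P,
    tip_radius_um = spec$tip_radius_um, poisson_ratio = spec$poisson_ratio,
    meta = spec$meta,
    ground_truth = list(params = spec$params, profile = pr,
                        contact_index = contact_index, spec = spec)
  )
}

#' Cohort design for hierarchical synthetic indentation data
#'
#' One row per group x structure cell. Specimen-level instantaneous moduli
#' and elastic fractions are drawn from the between-specimen distribution,
#' indent-level values from the within-specimen distribution around them.
#'
#' @param group,structure,level,stage Character vectors (recycled to a
#'   common length) labelling each cell.
#' @param mean_E_ins_kPa,mean_f Cell means of the instantaneous modulus and
#'   elastic fraction.
#' @param sd_E_ins_between_kPa,sd_E_ins_within_kPa Between-specimen and
#'   within-specimen SDs of E_ins.
#' @param sd_f_between,sd_f_within Same for the elastic fraction.
#' @param tau1_s Relaxation time assigned to every indent (not constrained
#'   by group summary tables; 2 s resolves the hold decay well within a
#'   10 s hold).
#' @param n_specimens Specimens per group (>= 1); default 3.
#' @param n_indents Indents per structure per specimen (>= 1); default 6.
#' @return A tibble of class `cohort_spec`.
#' @export
cohort_spec <- function(group, structure, level = NA_character_,
                        stage = NA_character_,
                        mean_E_ins_kPa, mean_f,
                        sd_E_ins_between_kPa = 0, sd_E_ins_within_kPa = 0,
                        sd_f_between = 0, sd_f_within = 0,
                        tau1_s = 2, n_specimens = 3, n_indents = 6) {
  out <- tibble(group = group, structure = structure, level = level,
                stage = stage, mean_E_ins_kPa = mean_E_ins_kPa,
                mean_f = mean_f,
                sd_E_ins_between_kPa = sd_E_ins_between_kPa,
                sd_E_ins_within_kPa = sd_E_ins_within_kPa,
                sd_f_between = sd_f_between, sd_f_within = sd_f_within,
                tau1_s = tau1_s, n_specimens = n_specimens,
                n_indents = n_indents)
  sds <- c(out$sd_E_ins_between_kPa, out$sd_E_ins_within_kPa,
           out$sd_f_between, out$sd_f_within)
  if (any(sds < 0)) {
    abort("Cohort SDs must be >= 0.", class = "ivdmech_error_invalid_spec")
  }
  if (any(out$n_specimens < 1) || any(out$n_indents < 1)) {
    abort("n_specimens and n_indents must be >= 1.",
          class = "ivdmech_error_invalid_spec")
  }
  class(out) <- c("cohort_spec", class(out))
  out
}

#' Built-in cervical-spine cohort design (TS24)
#'
#' Cell means and SDs of instantaneous modulus and elastic fraction for
#' vertebral bodies C5 and C6 and the C5-C6 annulus fibrosus in control and
#' muscular-dysgenesis (mdg) mouse embryos at Theiler stage 24, with 3
#' specimens per group and 6 indents per structure. The single published SD
#' per cell is split into equal between- and within-specimen variance
#' shares (each SD / sqrt(2)).
#'
#' @param n_specimens,n_indents Override the nested design sizes.
#' @param tau1_s Relaxation time given to every indent.
#' @return A [cohort_spec()] tibble with 6 rows.
#' @export
cervical_cohort_spec <- function(n_specimens = 3, n_indents = 6, tau1_s = 2) {
  s2 <- sqrt(2)
  cohort_spec(
    group = rep(c("control", "mdg"), times = 3),
    structure = rep(c("VB", "VB", "AF"), each = 2),
    level = rep(c("C5", "C6", "C5-C6"), each = 2),
    stage = "TS24",
    mean_E_ins_kPa = c(29, 30, 29, 27, 24, 37),
    mean_f = c(0.78, 0.74, 0.78, 0.77, 0.74, 0.67),
    sd_E_ins_between_kPa = c(7.3, 15, 14, 9.5, 4.9, 21) / s2,
    sd_E_ins_within_kPa = c(7.3, 15, 14, 9.5, 4.9, 21) / s2,
    sd_f_between = c(0.046, 0.055, 0.024, 0.069, 0.042, 0.076) / s2,
    sd_f_within = c(0.046, 0.055, 0.024, 0.069, 0.042, 0.076) / s2,
    tau1_s = tau1_s, n_specimens = n_specimens, n_indents = n_indents
  )
}

# exact truncated normal via the inverse-CDF method (no boundary point mass)
rnorm_trunc <- function(n, mean, sd, lo, hi = Inf) {
  if (sd == 0) return(pmin(pmax(rep(mean, n), lo), hi))
  p_lo <- stats::pnorm(lo, mean, sd)
  p_hi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(runif(n, p_lo, p_hi), mean, sd)
}

#' Generate a nested cohort of synthetic indentation records
#'
#' For every cell of the design, specimen-level parameters are drawn from
#' the between-specimen distribution and indent-level parameters from the
#' within-specimen distribution, then each indent is forward-simulated with
#' [generate_indent_curve()]. Every record carries its group, specimen,
#' structure, level and stage; the tibble also keeps the true parameters.
#'
#' @param spec A [cohort_spec()].
#' @param seed RNG seed governing all draws (specimen, indent and noise).
#' @param profile Displacement command shared by all indents.
#' @param noise_sd_uN Force noise SD (uN) per curve; default 0.001.
#' @param baseline_duration_s Pre-contact baseline per curve (s).
#' @param sample_rate_hz Sampling rate (Hz).
#' @param tip_radius_um,poisson_ratio Probe geometry.
#' @return A tibble with one row per indent: metadata columns, true
#'   parameter columns (`true_E_ins_kPa`, `true_f`, `true_tau1_s`) and a
#'   `record` list-column of [indent_record()] objects.
#' @export
generate_cohort <- function(spec, seed = NULL, profile = indent_profile(),
                            noise_sd_uN = 0.001, baseline_duration_s = 1,
                            sample_rate_hz = 100, tip_radius_um = 42,
                            poisson_ratio = 0.5) {
  stopifnot(inherits(spec, "cohort_spec"))
  gen <- function() {
    rows <- purrr::pmap(spec, function(group, structure, level, stage,
                                       mean_E_ins_kPa, mean_f,
                                       sd_E_ins_between_kPa,
                                       sd_E_ins_within_kPa,
                                       sd_f_between, sd_f_within, tau1_s,
                                       n_specimens, n_indents) {
      purrr::map(seq_len(n_specimens), function(s) {
        spec_id <- sprintf("%s_%s_s%d", group, stage %||% "NA", s)
        E_s <- rnorm_trunc(1, mean_E_ins_kPa, sd_E_ins_between_kPa, 1, Inf)
        f_s <- rnorm_trunc(1, mean_f, sd_f_between, 0.02, 0.98)
        E_i <- rnorm_trunc(n_indents, E_s, sd_E_ins_within_kPa, 1, Inf)
        f_i <- rnorm_trunc(n_indents, f_s, sd_f_within, 0.02, 0.98)
        recs <- purrr::map(seq_len(n_indents), function(k) {
          generate_indent_curve(synthetic_indent_spec(
            sls_params(f_i[k] * E_i[k], (1 - f_i[k]) * E_i[k], tau1_s),
            profile = profile, tip_radius_um = tip_radius_um,
            poisson_ratio = poisson_ratio,
            baseline_duration_s = baseline_duration_s,
            noise_sd_uN = noise_sd_uN, sample_rate_hz = sample_rate_hz,
            meta = list(group = group, specimen = spec_id,
                        structure = structure, level = level, stage = stage)
          ))
        })
        tibble(group = group, specimen = spec_id, structure = structure,
               level = level, stage = stage, indent = seq_len(n_indents),
               true_E_ins_kPa = E_i, true_f = f_i, true_tau1_s = tau1_s,
               record = recs)
      }) |> purrr::list_rbind()
    })
    purrr::list_rbind(rows)
  }
  if (!is.null(seed)) withr::with_seed(seed, gen()) else gen()
}

#' Fit every indent of a cohort
#'
#' Runs contact detection and [fit_sls()] over the `record` list-column of
#' a [generate_cohort()] tibble (or any tibble shaped like it). Fit
#' failures are caught and returned as rows with `converged = FALSE`.
#'
#' @param cohort Tibble with a `record` list-column plus metadata columns.
#' @param ... Passed to [fit_sls()].
#' @return The input tibble without `record`, with fitted columns
#'   `E_ins_kPa`, `E_eq_kPa`, `f`, `tau1_s`, `rmse_uN`, `r_squared`,
#'   `converged` appended.
#' @export
fit_cohort <- function(cohort, ...) {
  stopifnot("record" %in% names(cohort))
  fits <- purrr::map(cohort$record, function(rec) {
    tryCatch({
      ft <- fit_sls(rec, ...)
      tibble(E_ins_kPa = ft$E_ins_kPa, E_eq_kPa = ft$E_eq_kPa, f = ft$f,
             tau1_s = ft$params$tau1_s, rmse_uN = ft$rmse_uN,
             r_squared = ft$r_squared, converged = ft$converged)
    }, error = function(e) {
      tibble(E_ins_kPa = NA_real_, E_eq_kPa = NA_real_, f = NA_real_,
             tau1_s = NA_real_, rmse_uN = NA_real_, r_squared = NA_real_,
             converged = FALSE)
    })
  })
  dplyr::bind_cols(dplyr::select(cohort, -"record"), purrr::list_rbind(fits))
}
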