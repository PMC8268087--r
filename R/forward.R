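# Forward viscoelastic model for spherical ramp-hold indentation.
#
# Working units throughout: length um, time s, modulus kPa, force uN.
# In (um, kPa) the Hertz prefactor (4/3)*sqrt(R)*E* yields force in nN,
# hence the single /1000 inside hertz_prefactor().

# Dawson integral D(x) = exp(-x^2) * int_0^x exp(t^2) dt.
# pracma::erfi overflows for x >~ 27; switch to the asymptotic series
# well before that. Validated to < 1e-11 relative error at the crossover.
dawson_fn <- function(x) {
  stopifnot(all(x >= 0))
  out <- numeric(length(x))
  small <- x < 6
  if (any(small)) {
    xs <- x[small]
    out[small] <- exp(-xs^2) * pracma::erfi(xs) * sqrt(pi) / 2
  }
  if (any(!small)) {
    xb <- x[!small]
    s <- rep(1, length(xb))
    term <- rep(1, length(xb))
    for (k in 1:14) {
      term <- term * (2 * k - 1) / (2 * xb^2)
      s <- s + term
    }
    out[!small] <- s / (2 * xb)
  }
  out
}

# e^{-t/tau} * int_0^t e^{u/tau} sqrt(u) du, evaluated without overflow:
# substitute u = tau s^2 to get tau^{3/2} (x - D(x)) with x = sqrt(t/tau).
ramp_memory_integral <- function(t, tau1) {
  x <- sqrt(t / tau1)
  tau1^1.5 * (x - dawson_fn(x))
}

#' Trapezoidal displacement command profile
#'
#' Describes the displacement-controlled indentation profile: a constant-rate
#' loading ramp to the maximum depth, a constant-displacement hold, and a
#' constant-rate unload. Defaults are a 2 um/s ramp to 2 um, a 10 s hold
#' and a 2 um/s unload.
#'
#' @param v_load_um_s Loading ramp speed (um/s).
#' @param h_max_um Maximum indentation depth (um).
#' @param t_hold_s Hold duration at maximum depth (s).
#' @param v_unload_um_s Unloading speed (um/s).
#'
#' @return An object of class `indent_profile`: a list with the four fields
#'   above plus the derived ramp duration `t_ramp_s = h_max_um / v_load_um_s`.
#' @examples
#' indent_profile()
#' @export
indent_profile <- function(v_load_um_s = 2, h_max_um = 2, t_hold_s = 10,
                           v_unload_um_s = 2) {
  vals <- c(v_load_um_s, h_max_um, t_hold_s, v_unload_um_s)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("All profile fields must be strictly positive and finite.",
          class = "ivdmech_error_invalid_spec")
  }
  structure(
    list(v_load_um_s = v_load_um_s, h_max_um = h_max_um,
         t_hold_s = t_hold_s, v_unload_um_s = v_unload_um_s,
         t_ramp_s = h_max_um / v_load_um_s),
    class = "indent_profile"
  )
}

#' Standard-linear-solid relaxation parameters
#'
#' The standard linear solid (SLS) is a spring of modulus `E0` in parallel
#' with a Maxwell arm (spring `E1` in series with a dashpot), giving the
#' relaxation function G(t) = E0 + E1 exp(-t/tau1).
#'
#' @param E0_kPa Equilibrium spring modulus (kPa), `>= 0`.
#' @param E1_kPa Maxwell-arm spring modulus (kPa), `>= 0`.
#' @param tau1_s Maxwell relaxation time (s), `> 0`.
#'
#' @return An object of class `sls_params`.
#' @seealso [derived_moduli()], [sls_relaxation()]
#' @examples
#' sls_params(18, 6, 2)
#' @export
sls_params <- function(E0_kPa, E1_kPa, tau1_s) {
  if (!is.finite(E0_kPa) || !is.finite(E1_kPa) || !is.finite(tau1_s) ||
      E0_kPa < 0 || E1_kPa < 0 || tau1_s <= 0) {
    abort("Require E0 >= 0, E1 >= 0, tau1 > 0 (all finite).",
          class = "ivdmech_error_invalid_spec")
  }
  structure(list(E0_kPa = E0_kPa, E1_kPa = E1_kPa, tau1_s = tau1_s),
            class = "sls_params")
}

#' Derived moduli of a standard linear solid
#'
#' The instantaneous modulus is G(0) = E0 + E1, the equilibrium modulus is
#' G(Inf) = E0, and the elastic fraction f = E_eq / E_ins lies in `[0, 1]`:
#' f = 1 is a purely elastic material, f = 0 a purely viscous (Maxwell) one.
#'
#' @param params An [sls_params()] object, or the value of `E0_kPa`.
#' @param E1_kPa,tau1_s Used only when `params` is given as a bare `E0` value.
#'
#' @return A one-row tibble with columns `E_ins_kPa`, `E_eq_kPa`, `f`.
#' @examples
#' derived_moduli(sls_params(18, 6, 2)) # E_ins 24, E_eq 18, f 0.75
#' @export
derived_moduli <- function(params, E1_kPa = NULL, tau1_s = 1) {
  if (!inherits(params, "sls_params")) {
    params <- sls_params(params, E1_kPa, tau1_s)
  }
  E_ins <- params$E0_kPa + params$E1_kPa
  if (E_ins == 0) {
    abort("Elastic fraction undefined: E0 + E1 = 0.",
          class = "ivdmech_error_undefined_fraction")
  }
  tibble(E_ins_kPa = E_ins, E_eq_kPa = params$E0_kPa,
         f = params$E0_kPa / E_ins)
}

#' SLS relaxation function
#'
#' @param t_s Times (s), `>= 0`.
#' @param params An [sls_params()] object.
#' @return G(t) = E0 + E1 exp(-t/tau1) in kPa; monotone non-increasing.
#' @examples
#' sls_relaxation(c(0, 2, Inf), sls_params(18, 6, 2))
#' @export
sls_relaxation <- function(t_s, params) {
  stopifnot(inherits(params, "sls_params"))
  if (any(t_s < 0)) abort("t must be >= 0.", class = "ivdmech_error_domain")
  params$E0_kPa + params$E1_kPa * exp(-t_s / params$tau1_s)
}

hertz_prefactor <- function(tip_radius_um, poisson_ratio) {
  (4 * sqrt(tip_radius_um)) / (3 * (1 - poisson_ratio^2)) / 1000
}

#' Hertzian force for a rigid sphere on an elastic half-space
#'
#' P = (4/3) sqrt(R) E* h^(3/2) with reduced modulus E* = E / (1 - nu^2).
#'
#' @param h_um Indentation depth(s) (um), `>= 0`.
#' @param tip_radius_um Tip radius R (um).
#' @param E_kPa Young's modulus (kPa).
#' @param poisson_ratio Poisson's ratio nu; 0.5 assumes incompressibility.
#' @return Force in uN.
#' @examples
#' hertz_force(2, tip_radius_um = 42, E_kPa = 30, poisson_ratio = 0.5)
#' @export
hertz_force <- function(h_um, tip_radius_um, E_kPa, poisson_ratio = 0.5) {
  if (any(h_um < 0)) {
    abort("Indentation depth must be >= 0.", class = "ivdmech_error_domain")
  }
  hertz_prefactor(tip_radius_um, poisson_ratio) * E_kPa * h_um^1.5
}

#' Force response of an SLS half-space to a ramp-hold indentation
#'
#' Elastic-viscoelastic correspondence replaces the modulus in the Hertz
#' solution with a Boltzmann hereditary integral over the relaxation
#' function, P(t) = K int_0^t G(t-u) d(h(u)^{3/2})/du du with
#' K = 4 sqrt(R) / (3 (1 - nu^2)), solved separately on the loading ramp
#' (h = v t) and the hold (h = h_max). The ramp-phase memory integral is
#' evaluated in closed form through the Dawson function; an adaptive
#' quadrature route is provided for cross-validation and agrees with the
#' closed form to better than 1e-8 relative.
#'
#' @param t_s Times (s) within `[0, t_ramp + t_hold]`; the unload phase is
#'   outside the model's domain.
#' @param profile An [indent_profile()].
#' @param params An [sls_params()].
#' @param tip_radius_um Tip radius (um).
#' @param poisson_ratio Poisson's ratio.
#' @param method `"closed-form"` (default) or `"quadrature"`.
#' @return Force series in uN.
#' @examples
#' forward_ramp_hold(c(0.5, 1, 6), indent_profile(), sls_params(18, 6, 2))
#' @export
forward_ramp_hold <- function(t_s, profile, params, tip_radius_um = 42,
                              poisson_ratio = 0.5,
                              method = c("closed-form", "quadrature")) {
  method <- match.arg(method)
  stopifnot(inherits(profile, "indent_profile"), inherits(params, "sls_params"))
  t_R <- profile$t_ramp_s
  t_end <- t_R + profile$t_hold_s
  if (any(t_s < 0) || any(t_s > t_end + 1e-9)) {
    abort("t outside [0, ramp end + hold]; the unload phase is not modelled.",
          class = "ivdmech_error_domain")
  }
  K <- hertz_prefactor(tip_radius_um, poisson_ratio)
  v <- profile$v_load_um_s
  h_max <- profile$h_max_um
  E0 <- params$E0_kPa; E1 <- params$E1_kPa; tau1 <- params$tau1_s

  if (method == "quadrature") {
    return(vapply(t_s, function(tt) {
      up <- min(tt, t_R)
      if (up <= 0) return(0)
      val <- integrate(function(u) {
        (E0 + E1 * exp(-(tt - u) / tau1)) * 1.5 * v^1.5 * sqrt(u)
      }, 0, up, rel.tol = 1e-12, abs.tol = 0)$value
      K * val
    }, numeric(1)))
  }

  P <- numeric(length(t_s))
  ramp <- t_s <= t_R
  if (any(ramp)) {
    tr <- t_s[ramp]
    P[ramp] <- K * (E0 * (v * tr)^1.5 +
                      E1 * 1.5 * v^1.5 * ramp_memory_integral(tr, tau1))
  }
  if (any(!ramp)) {
    th <- t_s[!ramp]
    A_R <- ramp_memory_integral(t_R, tau1)
    P[!ramp] <- K * (E0 * h_max^1.5 +
                       E1 * 1.5 * v^1.5 * A_R * exp(-(th - t_R) / tau1))
  }
  P
}

# Displacement command of the full trapezoid (approach/ramp/hold/unload),
# with t = 0 at the start of the record and contact at t = baseline_s.
# Pre-contact the command is negative (tip above the surface).
command_displacement <- function(t_s, profile, baseline_s = 0) {
  tc <- t_s - baseline_s
  t_R <- profile$t_ramp_s
  t_HE <- t_R + profile$t_hold_s
  h <- profile$v_load_um_s * tc
  h[tc > t_R] <- profile$h_max_um
  un <- tc > t_HE
  h[un] <- profile$h_max_um - profile$v_unload_um_s * (tc[un] - t_HE)
  h
}
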