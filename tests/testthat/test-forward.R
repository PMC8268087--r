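# Forward model: Hertz contact, SLS relaxation, hereditary integral.

test_that("hertz_force matches direct arithmetic and is linear in E", {
  # (4/3) * sqrt(42) * (30 / (1 - 0.25)) * 2^1.5 nN = 0.9778 uN
  expect_equal(hertz_force(2, 42, 30, 0.5),
               (4 / 3) * sqrt(42) * 40 * 2^1.5 / 1000, tolerance = 1e-12)
  expect_equal(hertz_force(0, 42, 30, 0.5), 0)
  h <- c(0.1, 0.7, 2)
  expect_equal(hertz_force(h, 42, 60, 0.5), 2 * hertz_force(h, 42, 30, 0.5))
  expect_error(hertz_force(-0.1, 42, 30), class = "ivdmech_error_domain")
})

test_that("sls_relaxation has the right limits and arithmetic value", {
  p <- sls_params(18, 6, 2)
  expect_equal(sls_relaxation(0, p), 24)
  expect_equal(sls_relaxation(1e9, p), 18)
  expect_equal(sls_relaxation(2, p), 18 + 6 / exp(1), tolerance = 1e-12)
  t <- seq(0, 30, by = 0.1)
  expect_true(all(diff(sls_relaxation(t, p)) <= 0))
  expect_error(sls_relaxation(-1, p), class = "ivdmech_error_domain")
})

test_that("derived moduli and elastic fraction follow their definitions", {
  m <- derived_moduli(sls_params(18, 6, 2))
  expect_equal(m$E_ins_kPa, 24)
  expect_equal(m$E_eq_kPa, 18)
  expect_equal(m$f, 0.75)
  expect_equal(derived_moduli(sls_params(40, 0, 1))$f, 1)
  expect_error(derived_moduli(sls_params(0, 0, 1)),
               class = "ivdmech_error_undefined_fraction")
})

test_that("elastic limit of the hereditary integral is the Hertz response", {
  prof <- indent_profile()
  p <- sls_params(40, 0, 2)
  t <- seq(0, prof$t_ramp_s + prof$t_hold_s, by = 0.05)
  h <- pmin(prof$v_load_um_s * t, prof$h_max_um)
  expect_equal(forward_ramp_hold(t, prof, p),
               hertz_force(h, 42, 40, 0.5), tolerance = 1e-10)
})

test_that("long holds relax to the equilibrium plateau, continuously at t_R", {
  prof <- indent_profile(t_hold_s = 100)
  p <- sls_params(18, 6, 2)
  P_end <- forward_ramp_hold(prof$t_ramp_s + prof$t_hold_s, prof, p)
  expect_equal(P_end, hertz_force(2, 42, 18, 0.5), tolerance = 1e-6)
  # continuity across the ramp/hold boundary
  eps <- 1e-9
  expect_equal(forward_ramp_hold(prof$t_ramp_s - eps, prof, p),
               forward_ramp_hold(prof$t_ramp_s + eps, prof, p),
               tolerance = 1e-6)
  # monotonicity: non-decreasing ramp, non-increasing hold, above plateau
  tr <- seq(0, prof$t_ramp_s, by = 0.01)
  th <- seq(prof$t_ramp_s, prof$t_ramp_s + prof$t_hold_s, by = 0.05)
  expect_true(all(diff(forward_ramp_hold(tr, prof, p)) >= 0))
  Ph <- forward_ramp_hold(th, prof, p)
  expect_true(all(diff(Ph) <= 0))
  expect_true(all(Ph >= hertz_force(2, 42, 18, 0.5) - 1e-12))
})

test_that("closed form matches brute-force trapezoid convolution to 1e-5", {
  prof <- indent_profile()
  p <- sls_params(18, 6, 2)
  # oracle: trapezoid rule on K G(t-u) d(h^{3/2})/du over 1e4 nodes
  oracle <- function(t1) {
    u <- seq(0, min(t1, prof$t_ramp_s), length.out = 1e4)
    g <- (p$E0_kPa + p$E1_kPa * exp(-(t1 - u) / p$tau1_s)) *
      1.5 * prof$v_load_um_s^1.5 * sqrt(u)
    (4 * sqrt(42)) / (3 * 0.75) / 1000 * pracma::trapz(u, g)
  }
  for (t1 in c(0.25, 0.7, 1, 3, 11)) {
    expect_equal(forward_ramp_hold(t1, prof, p), oracle(t1),
                 tolerance = 1e-5)
  }
})

test_that("closed-form and adaptive-quadrature routes agree to 1e-8", {
  # tau1 / t_ramp in {0.1, 1, 10}
  for (tau1 in c(0.1, 1, 10)) {
    prof <- indent_profile()
    p <- sls_params(18, 6, tau1)
    t <- c(seq(0.05, prof$t_ramp_s, length.out = 8),
           seq(prof$t_ramp_s + 0.1, prof$t_ramp_s + prof$t_hold_s,
               length.out = 5))
    cf <- forward_ramp_hold(t, prof, p)
    qd <- forward_ramp_hold(t, prof, p, method = "quadrature")
    expect_equal(cf, qd, tolerance = 1e-8)
  }
})

test_that("times beyond the hold are rejected", {
  prof <- indent_profile()
  expect_error(forward_ramp_hold(12, prof, sls_params(18, 6, 2)),
               class = "ivdmech_error_domain")
})

test_that("constructors enforce their invariants", {
  expect_error(indent_profile(v_load_um_s = 0),
               class = "ivdmech_error_invalid_spec")
  expect_error(sls_params(-1, 6, 2), class = "ivdmech_error_invalid_spec")
  expect_error(sls_params(18, 6, 0), class = "ivdmech_error_invalid_spec")
  expect_equal(indent_profile()$t_ramp_s, 1)
})
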