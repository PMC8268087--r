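# Synthetic-data generators: curves, cohorts, phantoms.

test_that("seeded generation is bit-identical", {
  spec <- synthetic_indent_spec(sls_params(18, 6, 2), noise_sd_uN = 0.002,
                                seed = 7)
  r1 <- generate_indent_curve(spec)
  r2 <- generate_indent_curve(spec)
  expect_identical(r1$force_uN, r2$force_uN)

  fs <- fiber_image_spec(n_fibers = 20, seed = 7, width_px = 128,
                         height_px = 128)
  expect_identical(generate_fiber_image(fs)$image,
                   generate_fiber_image(fs)$image)

  cs <- cohort_spec("g", "AF", mean_E_ins_kPa = 24, mean_f = 0.74,
                    sd_E_ins_between_kPa = 3, sd_f_within = 0.02,
                    n_specimens = 2, n_indents = 2)
  c1 <- generate_cohort(cs, seed = 3)
  c2 <- generate_cohort(cs, seed = 3)
  expect_identical(c1$true_E_ins_kPa, c2$true_E_ins_kPa)
  expect_identical(c1$record[[1]]$force_uN, c2$record[[1]]$force_uN)
})

test_that("noise-free elastic curve equals the Hertz response on the ramp", {
  rec <- noise_free_record(40, 0, 2, baseline = 1)
  gt <- attr(rec, "ground_truth")
  post <- rec$time_s >= 1 & rec$time_s <= 2   # the 1 s ramp
  h <- rec$displacement_um[post]
  expect_equal(rec$force_uN[post], hertz_force(h, 42, 40, 0.5),
               tolerance = 1e-10)
  expect_equal(gt$contact_index, 101)
})

test_that("noise-free curves agree with the forward model to 1e-6 relative", {
  rec <- noise_free_record(18, 6, 2, baseline = 1)
  prof <- indent_profile()
  post <- rec$time_s >= 1 & rec$time_s <= 12
  tc <- rec$time_s[post] - 1
  expect_equal(rec$force_uN[post],
               forward_ramp_hold(tc, prof, sls_params(18, 6, 2)),
               tolerance = 1e-6)
})

test_that("generator ground-truth contact is recoverable", {
  rec <- generate_indent_curve(synthetic_indent_spec(
    sls_params(18, 6, 2), baseline_duration_s = 5, noise_sd_uN = 5e-4,
    seed = 99))
  gt <- attr(rec, "ground_truth")
  expect_equal(gt$contact_index, 501)
  expect_lte(abs(detect_contact(rec)$index - gt$contact_index), 10)
})

test_that("invalid curve specs are rejected", {
  expect_error(synthetic_indent_spec(sls_params(18, 6, 2),
                                     sample_rate_hz = 0),
               class = "ivdmech_error_invalid_spec")
  expect_error(synthetic_indent_spec(sls_params(18, 6, 2),
                                     noise_sd_uN = -1),
               class = "ivdmech_error_invalid_spec")
  expect_error(sls_params(18, 6, -2), class = "ivdmech_error_invalid_spec")
})

test_that("cohort counting and nesting are conserved", {
  cs <- cohort_spec(c("a", "b"), "AF", mean_E_ins_kPa = c(24, 37),
                    mean_f = c(0.74, 0.67), n_specimens = 3, n_indents = 6)
  co <- generate_cohort(cs, seed = 1)
  expect_equal(nrow(co), 2 * 3 * 6)
  counts <- dplyr::count(co, group, structure)
  expect_true(all(counts$n == 18))
  # each indent belongs to exactly one specimen, each specimen to one group
  nest <- dplyr::distinct(co, specimen, group)
  expect_equal(nrow(nest), dplyr::n_distinct(co$specimen))
})

test_that("zero-SD cohorts return the group mean from every fit", {
  cs <- cohort_spec("a", "AF", mean_E_ins_kPa = 24, mean_f = 0.74,
                    n_specimens = 2, n_indents = 2)
  co <- generate_cohort(cs, seed = 5, noise_sd_uN = 0)
  fits <- fit_cohort(co)
  expect_true(all(fits$converged))
  expect_equal(fits$E_ins_kPa, rep(24, 4), tolerance = 1e-3)
  expect_equal(fits$f, rep(0.74, 4), tolerance = 1e-3)
})

test_that("negative cohort SDs are rejected", {
  expect_error(cohort_spec("a", "AF", mean_E_ins_kPa = 24, mean_f = 0.7,
                           sd_f_between = -0.1),
               class = "ivdmech_error_invalid_spec")
})

test_that("cohort Monte-Carlo recovers the design means of f", {
  # control-AF f = 0.74, mdg-AF f = 0.67, SDs split from the published
  # totals (0.042 and 0.076); grand fitted means within 2 SE over 20 seeds
  cs <- cervical_cohort_spec()
  cs <- cs[cs$structure == "AF", ]
  gm <- matrix(NA_real_, 20, 2)
  for (s in 1:20) {
    co <- generate_cohort(cs, seed = 500 + s)
    fits <- fit_cohort(co)
    gm[s, ] <- c(mean(fits$f[fits$group == "control"], na.rm = TRUE),
                 mean(fits$f[fits$group == "mdg"], na.rm = TRUE))
  }
  for (j in 1:2) {
    se <- sd(gm[, j]) / sqrt(nrow(gm))
    expect_lt(abs(mean(gm[, j]) - c(0.74, 0.67)[j]), 2 * se + 1e-3)
  }
})

test_that("fiber phantoms carry recoverable per-quadrant ground truth", {
  quads <- tibble::tibble(
    quadrant = c("cranial-dorsal", "cranial-ventral", "caudal-dorsal",
                 "caudal-ventral"),
    angle_mean_deg = c(90, 90, 150, 30), angle_sd_deg = 0)
  fim <- generate_fiber_image(fiber_image_spec(
    width_px = 256, height_px = 256, n_fibers = 120, quadrants = quads,
    seed = 11))
  fld <- apply_masks(fim$image, orientation_field(fim$image))
  qs <- quadrant_summaries(fld, split_quadrants(dim(fim$image)))
  for (q in seq_len(nrow(quads))) {
    got <- qs$circular_mean_deg[qs$quadrant == quads$quadrant[q]]
    d <- abs(((got - quads$angle_mean_deg[q] + 90) %% 180) - 90)
    expect_lt(d, 3)
  }
})

test_that("pure-background phantoms carry no orientation signal", {
  # noise-free background: coherency identically zero, mask exactly empty
  expect_warning(
    fim0 <- generate_fiber_image(fiber_image_spec(
      width_px = 128, height_px = 128, n_fibers = 0, noise_sd = 0, seed = 2)),
    "pure-background")
  fld0 <- apply_masks(fim0$image, orientation_field(fim0$image))
  expect_false(any(fld0$valid_mask))
  expect_equal(nrow(fim0$angles), 0)

  # noisy background: surviving pixels sit in a handful of coherent noise
  # blobs (window sigma sets the blob scale), so only weak alignment is
  # possible -- nothing close to a structured phantom's resultant
  fim <- suppressWarnings(generate_fiber_image(fiber_image_spec(
    width_px = 256, height_px = 256, n_fibers = 0, noise_sd = 0.01,
    seed = 2)))
  fld <- apply_masks(fim$image, orientation_field(fim$image))
  if (any(fld$valid_mask)) {
    s <- circular_summary(fld$theta_deg[fld$valid_mask])
    expect_lt(s$resultant_length, 0.5)
  }
})
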