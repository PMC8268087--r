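# Structure-tensor orientation, masking and quadrant partitioning.

test_that("max projection is the pixelwise maximum", {
  a <- matrix(0, 8, 8); a[2, 2] <- 1
  b <- matrix(0, 8, 8); b[5, 7] <- 2
  expect_identical(max_project(list(a)), a)
  m <- max_project(list(a, b))
  expect_equal(m[2, 2], 1)
  expect_equal(m[5, 7], 2)
  set.seed(1)
  st <- array(runif(8 * 8 * 4), dim = c(8, 8, 4))
  mp <- max_project(st)
  for (k in 1:4) expect_true(all(mp >= st[, , k]))
})

test_that("gratings along known angles are recovered within 1 degree", {
  for (ang in c(30, 89, 120, 1)) {
    img <- grating_image(200, ang)
    fld <- orientation_field(img, window_sigma_px = 10)
    m <- field_axial_mean(img, fld, border = 40)
    d <- abs(((m - ang + 90) %% 180) - 90)
    expect_lt(d, 1)
  }
})

test_that("uniform images have zero coherency and no defined angle", {
  img <- matrix(0.7, 128, 128)
  fld <- orientation_field(img)
  expect_true(all(fld$coherency == 0))
  expect_true(all(is.na(fld$theta_deg)))
  expect_false(any(fld$valid_mask))
})

test_that("orientation is invariant to affine intensity rescaling", {
  img <- grating_image(150, 40)
  f1 <- orientation_field(img)
  f2 <- orientation_field(3 * img + 10)
  expect_equal(field_axial_mean(img, f1, 30),
               field_axial_mean(img, f2, 30), tolerance = 1e-6)
})

test_that("rotating the image rotates the recovered orientation (20 deg)", {
  img <- grating_image(256, 30, period = 16)
  rot <- rotate_image(img, 20, background = 0.5)
  f0 <- orientation_field(img)
  f1 <- orientation_field(rot)
  m0 <- field_axial_mean(img, f0, border = 80)
  m1 <- field_axial_mean(rot, f1, border = 80)
  shift <- ((m1 - m0 + 90) %% 180) - 90
  expect_equal(shift, 20, tolerance = 1)
})

test_that("cubic-spline and central-difference gradients agree on phantoms", {
  img <- grating_image(180, 65, period = 14)
  ms <- field_axial_mean(img, orientation_field(img, "cubic-spline"), 36)
  mc <- field_axial_mean(img, orientation_field(img, "central-diff"), 36)
  expect_lt(abs(((ms - mc + 90) %% 180) - 90), 2)
})

test_that("masks use strict thresholds and are monotone", {
  img <- grating_image(128, 30)
  img[1:20, 1:20] <- 0.05 * max(img)    # exactly at the intensity bound
  fld <- orientation_field(img)
  masked <- apply_masks(img, fld)
  expect_false(any(masked$valid_mask[1:10, 1:10]))
  # coherency exactly at the bound is excluded
  fld2 <- fld
  fld2$coherency[] <- 0.05
  m2 <- apply_masks(img, fld2)
  expect_false(any(m2$valid_mask))
  # monotone: raising a threshold never adds pixels
  loose <- apply_masks(img, fld, intensity_frac = 0.02, coherency_min = 0.02)
  tight <- apply_masks(img, fld, intensity_frac = 0.10, coherency_min = 0.20)
  expect_true(all(loose$valid_mask >= tight$valid_mask))
  # all-zero image -> empty mask
  z <- matrix(0, 128, 128)
  expect_false(any(apply_masks(z, orientation_field(z))$valid_mask))
})

test_that("coherency lies in [0, 1]", {
  set.seed(4)
  img <- matrix(runif(128 * 128), 128, 128)
  fld <- orientation_field(img)
  expect_true(all(fld$coherency >= 0 & fld$coherency <= 1))
})

test_that("quadrant split tiles the ROI with the documented tie-break", {
  p <- split_quadrants(c(100, 80))
  expect_equal(nrow(p), 4)
  expect_true(all(p$row_max - p$row_min + 1 == 50))
  expect_true(all(p$col_max - p$col_min + 1 == 40))
  # disjoint tiling covers every pixel exactly once
  cover <- matrix(0L, 100, 80)
  for (i in 1:4) {
    cover[p$row_min[i]:p$row_max[i], p$col_min[i]:p$col_max[i]] <-
      cover[p$row_min[i]:p$row_max[i], p$col_min[i]:p$col_max[i]] + 1L
  }
  expect_true(all(cover == 1L))

  # odd dimension: extra pixel to the caudal half
  p2 <- split_quadrants(c(101, 80))
  cr <- p2[p2$quadrant == "cranial-dorsal", ]
  cd <- p2[p2$quadrant == "caudal-dorsal", ]
  expect_equal(cr$row_max - cr$row_min + 1, 50)
  expect_equal(cd$row_max - cd$row_min + 1, 51)
})

test_that("flipping dorsoventral polarity swaps dorsal/ventral labels only", {
  a <- split_quadrants(c(100, 80))
  b <- split_quadrants(c(100, 80), axis_convention(dorsal = "last"))
  for (cc in c("cranial", "caudal")) {
    da <- a[a$quadrant == paste0(cc, "-dorsal"), -1]
    vb <- b[b$quadrant == paste0(cc, "-ventral"), -1]
    expect_equal(as.numeric(da), as.numeric(vb))
  }
})

test_that("too-small images and ROIs are rejected", {
  expect_error(orientation_field(matrix(0, 30, 30), window_sigma_px = 10),
               class = "ivdmech_error_data")
  expect_error(split_quadrants(list(rows = c(1, 1), cols = c(1, 10))),
               class = "ivdmech_error_data")
})
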