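# Shared fixtures: analytic phantoms and small utilities.

# noise-free record for given SLS parameters (baseline optional)
noise_free_record <- function(E0, E1, tau1, baseline = 0, ...) {
  generate_indent_curve(synthetic_indent_spec(
    sls_params(E0, E1, tau1), baseline_duration_s = baseline, ...))
}

# sinusoidal grating whose stripes run ALONG `angle_deg` (x-axis = columns,
# angles counter-clockwise, y up), period in px
grating_image <- function(n, angle_deg, period = 12) {
  a <- angle_deg * pi / 180
  cc <- outer(rep(1, n), seq_len(n))          # x (column)
  yy <- n - outer(seq_len(n), rep(1, n)) + 1  # y up
  phase <- (-sin(a)) * cc + cos(a) * yy       # coordinate across stripes
  0.5 + 0.5 * sin(2 * pi * phase / period)
}

# bilinear rotation about the image centre (y-up convention, CCW by deg);
# pixels sampled outside the source keep the background value
rotate_image <- function(img, deg, background = 0) {
  nr <- nrow(img); nc <- ncol(img)
  a <- deg * pi / 180
  cx <- (nc + 1) / 2; cy <- (nr + 1) / 2
  out <- matrix(background, nr, nc)
  cols <- outer(rep(1, nr), seq_len(nc))
  rows <- outer(seq_len(nr), rep(1, nc))
  x <- cols - cx
  y <- (nr - rows + 1) - cy
  # inverse map: rotate by -deg
  xs <- cos(-a) * x - sin(-a) * y + cx
  ys <- sin(-a) * x + cos(-a) * y + cy
  rs <- nr - ys + 1
  x0 <- floor(xs); y0 <- floor(rs)
  fx <- xs - x0; fy <- rs - y0
  ok <- x0 >= 1 & x0 + 1 <= nc & y0 >= 1 & y0 + 1 <= nr
  idx <- function(r, c) (c - 1) * nr + r
  v <- background + numeric(nr * nc)
  v[ok] <- (1 - fx[ok]) * (1 - fy[ok]) * img[idx(y0[ok], x0[ok])] +
    fx[ok] * (1 - fy[ok]) * img[idx(y0[ok], x0[ok] + 1)] +
    (1 - fx[ok]) * fy[ok] * img[idx(y0[ok] + 1, x0[ok])] +
    fx[ok] * fy[ok] * img[idx(y0[ok] + 1, x0[ok] + 1)]
  matrix(v, nr, nc)
}

# interior crop (drop a border of `b` px)
crop_border <- function(m, b) m[(b + 1):(nrow(m) - b), (b + 1):(ncol(m) - b)]

# masked circular mean of an orientation field over (optionally) a crop
field_axial_mean <- function(image, field, border = 0) {
  th <- field$theta_deg
  mask <- field$valid_mask
  if (border > 0) {
    th <- crop_border(th, border)
    mask <- crop_border(mask, border)
  }
  axial_mean_deg(th[mask])
}
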