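# Fibrous phantom images with known axial orientation ground truth.

#' Specification of a fibrous phantom image
#'
#' Describes a grayscale image of straight fibres with Gaussian
#' cross-section, whose axial orientations are drawn from a wrapped normal
#' on doubled angles. Angles follow the package convention: 0 deg is the
#' image x-axis (dorsoventral axis), increasing counter-clockwise, modulo
#' 180 deg.
#'
#' @param width_px,height_px Image size in pixels (>= 64 for meaningful
#'   structure-tensor windows).
#' @param n_fibers Total number of fibres (split evenly across quadrants
#'   when `quadrants` is given).
#' @param angle_mean_deg,angle_sd_deg Axial mean and SD of fibre angles.
#' @param fiber_width_px Full width of the Gaussian cross-section in px
#'   (the profile SD is half of this).
#' @param fiber_length_frac Fibre length as a fraction of the relevant
#'   region's smaller dimension.
#' @param fiber_intensity,background_intensity Peak fibre and flat
#'   background intensities (arbitrary units).
#' @param noise_sd SD of additive Gaussian pixel noise.
#' @param quadrants Optional tibble/data frame with columns `quadrant`
#'   (labels as in [split_quadrants()]), `angle_mean_deg`, `angle_sd_deg`
#'   overriding the global angle distribution per quadrant; fibre centres
#'   are then confined to their quadrant.
#' @param seed Optional RNG seed.
#' @return An object of class `fiber_image_spec`.
#' @export
fiber_image_spec <- function(width_px = 512, height_px = 512, n_fibers = 200,
                             angle_mean_deg = 90, angle_sd_deg = 10,
                             fiber_width_px = 3, fiber_length_frac = 0.5,
                             fiber_intensity = 1, background_intensity = 0.02,
                             noise_sd = 0.01, quadrants = NULL, seed = NULL) {
  if (width_px < 64 || height_px < 64) {
    abort("Phantom images must be at least 64 px in each dimension.",
          class = "ivdmech_error_invalid_spec")
  }
  if (n_fibers < 0 || angle_sd_deg < 0 || noise_sd < 0 || fiber_width_px <= 0) {
    abort("Invalid phantom spec: negative counts, SDs or widths.",
          class = "ivdmech_error_invalid_spec")
  }
  if (!is.null(quadrants)) {
    quadrants <- as_tibble(quadrants)
    need <- c("quadrant", "angle_mean_deg", "angle_sd_deg")
    if (!all(need %in% names(quadrants))) {
      abort("quadrants must have columns quadrant, angle_mean_deg, angle_sd_deg.",
            class = "ivdmech_error_invalid_spec")
    }
  }
  structure(
    list(width_px = width_px, height_px = height_px, n_fibers = n_fibers,
         angle_mean_deg = angle_mean_deg %% 180, angle_sd_deg = angle_sd_deg,
         fiber_width_px = fiber_width_px,
         fiber_length_frac = fiber_length_frac,
         fiber_intensity = fiber_intensity,
         background_intensity = background_intensity, noise_sd = noise_sd,
         quadrants = quadrants, seed = seed),
    class = "fiber_image_spec"
  )
}

# axial wrapped-normal draw: normal on doubled angles, halved back
draw_axial_angles <- function(n, mean_deg, sd_deg) {
  (rnorm(n, 2 * mean_deg, 2 * sd_deg) / 2) %% 180
}

# paint one anti-aliased fibre (Gaussian cross-section) into img.
# (cx, cy) in y-up coordinates; returns the updated matrix.
paint_fiber <- function(img, cx, cy, angle_deg, length_px, sigma_f, peak) {
  nr <- nrow(img); nc <- ncol(img)
  a <- angle_deg * pi / 180
  dx <- cos(a); dy <- sin(a)
  x0 <- cx - dx * length_px / 2; y0 <- cy - dy * length_px / 2
  x1 <- cx + dx * length_px / 2; y1 <- cy + dy * length_px / 2
  m <- 4 * sigma_f
  cs <- max(1, floor(min(x0, x1) - m)):min(nc, ceiling(max(x0, x1) + m))
  ys <- max(1, floor(min(y0, y1) - m)):min(nr, ceiling(max(y0, y1) + m))
  if (!length(cs) || !length(ys)) return(img)
  px <- outer(rep(1, length(ys)), cs)
  py <- outer(ys, rep(1, length(cs)))
  vx <- x1 - x0; vy <- y1 - y0; vv <- vx * vx + vy * vy
  tt <- pmin(pmax(((px - x0) * vx + (py - y0) * vy) / vv, 0), 1)
  d2 <- (px - (x0 + tt * vx))^2 + (py - (y0 + tt * vy))^2
  rows <- nr - ys + 1L   # y-up -> matrix row
  img[rows, cs] <- img[rows, cs] + peak * exp(-d2 / (2 * sigma_f^2))
  img
}

#' Generate a fibrous phantom image with known orientations
#'
#' Renders anti-aliased straight fibres at axial angles drawn from a
#' wrapped normal (on doubled angles), adds flat background and Gaussian
#' noise, and returns the drawn angles as ground truth. With a `quadrants`
#' table in the spec, each quadrant gets its own angle distribution and its
#' fibres are centred inside it (lengths capped so fibres mostly stay in
#' their quadrant).
#'
#' @param spec A [fiber_image_spec()].
#' @return A list of class `fiber_image`: `image` (matrix, rows x cols,
#'   row 1 at the top), `angles` (tibble with `fiber`, `quadrant`,
#'   `angle_deg`), `spec`.
#' @export
generate_fiber_image <- function(spec) {
  stopifnot(inherits(spec, "fiber_image_spec"))
  gen <- function() {
    nr <- spec$height_px; nc <- spec$width_px
    img <- matrix(spec$background_intensity, nr, nc)
    sigma_f <- spec$fiber_width_px / 2
    angles <- tibble(fiber = integer(), quadrant = character(),
                     angle_deg = numeric())

    if (spec$n_fibers == 0) {
      if (spec$fiber_intensity > 0) {
        warn("n_fibers = 0: returning a pure-background image.")
      }
    } else if (is.null(spec$quadrants)) {
      ang <- draw_axial_angles(spec$n_fibers, spec$angle_mean_deg,
                               spec$angle_sd_deg)
      L <- spec$fiber_length_frac * min(nr, nc)
      cx <- runif(spec$n_fibers, 1, nc)
      cy <- runif(spec$n_fibers, 1, nr)
      for (i in seq_len(spec$n_fibers)) {
        img <- paint_fiber(img, cx[i], cy[i], ang[i], L, sigma_f,
                           spec$fiber_intensity)
      }
      angles <- tibble(fiber = seq_len(spec$n_fibers),
                       quadrant = NA_character_, angle_deg = ang)
    } else {
      part <- split_quadrants(c(nr, nc))
      qn <- nrow(spec$quadrants)
      per <- diff(round(seq(0, spec$n_fibers, length.out = qn + 1)))
      fid <- 0L
      for (q in seq_len(qn)) {
        lab <- spec$quadrants$quadrant[q]
        box <- part[part$quadrant == lab, ]
        if (nrow(box) != 1) {
          abort(sprintf("Unknown quadrant label '%s'.", lab),
                class = "ivdmech_error_invalid_spec")
        }
        ang <- draw_axial_angles(per[q], spec$quadrants$angle_mean_deg[q],
                                 spec$quadrants$angle_sd_deg[q])
        ## y-up bounds of this quadrant
        ylo <- nr - box$row_max + 1L; yhi <- nr - box$row_min + 1L
        L <- spec$fiber_length_frac *
          min(box$row_max - box$row_min + 1L, box$col_max - box$col_min + 1L)
        cx <- runif(per[q], box$col_min, box$col_max)
        cy <- runif(per[q], ylo, yhi)
        for (i in seq_len(per[q])) {
          img <- paint_fiber(img, cx[i], cy[i], ang[i], L, sigma_f,
                             spec$fiber_intensity)
        }
        if (per[q] > 0) {
          angles <- dplyr::bind_rows(angles, tibble(
            fiber = fid + seq_len(per[q]), quadrant = lab, angle_deg = ang))
        }
        fid <- fid + per[q]
      }
    }

    if (spec$noise_sd > 0) {
      img <- img + matrix(rnorm(nr * nc, 0, spec$noise_sd), nr, nc)
    }
    img[img < 0] <- 0
    structure(list(image = img, angles = angles, spec = spec),
              class = "fiber_image")
  }
  if (!is.null(spec$seed)) withr::with_seed(spec$seed, gen()) else gen()
}

#' @export
print.fiber_image <- function(x, ...) {
  cat(sprintf("<fiber_image: %d x %d px, %d fibres>\n",
              nrow(x$image), ncol(x$image), nrow(x$angles)))
  invisible(x)
}
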