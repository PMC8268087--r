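# Structure-tensor orientation analysis.
#
# Image convention: matrices are row x col with row 1 at the top. Angles
# are axial, in degrees in [0, 180), measured counter-clockwise from the
# image x-axis (columns; the dorsoventral axis), i.e. in y-up coordinates.

#' Maximum-intensity projection of an image stack
#'
#' @param stack A list of equally sized matrices or a 3-d array with the
#'   slice index last.
#' @return A single matrix, the per-pixel maximum across slices.
#' @export
max_project <- function(stack) {
  if (is.array(stack) && length(dim(stack)) == 3) {
    stack <- lapply(seq_len(dim(stack)[3]), function(k) stack[, , k])
  }
  if (is.matrix(stack)) return(stack)
  if (!is.list(stack) || !length(stack)) {
    abort("Need at least one image slice.", class = "ivdmech_error_data")
  }
  Reduce(pmax, stack)
}

gauss_kernel <- function(sigma) {
  r <- ceiling(3 * sigma)
  x <- -r:r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

pad_reflect <- function(m, r) {
  ri <- c(rev(seq_len(r)) + 1L, seq_len(nrow(m)), nrow(m) - seq_len(r))
  ci <- c(rev(seq_len(r)) + 1L, seq_len(ncol(m)), ncol(m) - seq_len(r))
  m[ri, ci]
}

# separable convolution with reflective padding (shift-and-add)
conv_sep <- function(m, k) {
  r <- (length(k) - 1L) / 2L
  if (r == 0) return(m)
  nr <- nrow(m); nc <- ncol(m)
  mp <- pad_reflect(m, r)
  out1 <- matrix(0, nr, nc + 2L * r)
  for (i in seq_along(k)) out1 <- out1 + k[i] * mp[(i - 1L) + seq_len(nr), ]
  out <- matrix(0, nr, nc)
  for (i in seq_along(k)) out <- out + k[i] * out1[, (i - 1L) + seq_len(nc)]
  out
}

# derivative along columns of each row via a cubic-spline interpolant
spline_deriv_rows <- function(m) {
  nc <- ncol(m)
  xs <- seq_len(nc)
  t(apply(m, 1, function(row) {
    splinefun(xs, row, method = "natural")(xs, deriv = 1)
  }))
}

central_diff_rows <- function(m) {
  nc <- ncol(m)
  left <- m[, c(1L, seq_len(nc - 1L)), drop = FALSE]
  right <- m[, c(seq_len(nc - 1L) + 1L, nc), drop = FALSE]
  d <- (right - left) / 2
  d[, 1L] <- m[, 2L] - m[, 1L]
  d[, nc] <- m[, nc] - m[, nc - 1L]
  d
}

#' Per-pixel orientation and coherency via the structure tensor
#'
#' Image gradients are taken as derivatives of a separable cubic-spline
#' interpolant (a central-difference fallback is selectable); the tensor
#' components gx^2, gx gy, gy^2 are then averaged under a Gaussian window
#' (SD `window_sigma_px`, truncated at 3 sigma, reflective boundaries).
#' The reported angle is the direction *along* structures relative to the
#' x-axis, folded to `[0, 180)`; coherency is the normalized eigenvalue
#' anisotropy (lambda_max - lambda_min) / (lambda_max + lambda_min), set to
#' 0 where the tensor trace vanishes (e.g. constant images).
#'
#' @param image Numeric matrix (grayscale, row 1 at top); the smaller
#'   dimension must exceed 6 times the window SD.
#' @param gradient_method `"cubic-spline"` (default) or `"central-diff"`.
#' @param window_sigma_px Gaussian window SD in pixels; default 10.
#' @return Object of class `orientation_field`: matrices `theta_deg`
#'   (`NA` where undefined), `coherency`, logical `valid_mask`, plus the
#'   parameters used.
#' @export
orientation_field <- function(image,
                              gradient_method = c("cubic-spline",
                                                  "central-diff"),
                              window_sigma_px = 10) {
  gradient_method <- match.arg(gradient_method)
  stopifnot(is.matrix(image), is.numeric(image))
  if (min(dim(image)) <= 6 * window_sigma_px) {
    abort("Image smaller than 6 x window sigma; orientation not meaningful.",
          class = "ivdmech_error_data")
  }
  grad <- switch(gradient_method,
                 "cubic-spline" = spline_deriv_rows,
                 "central-diff" = central_diff_rows)
  gx <- grad(image)              # d/dx (x = column)
  gy <- -t(grad(t(image)))       # d/dy with y pointing up

  k <- gauss_kernel(window_sigma_px)
  Jxx <- conv_sep(gx * gx, k)
  Jyy <- conv_sep(gy * gy, k)
  Jxy <- conv_sep(gx * gy, k)

  tr <- Jxx + Jyy
  sq <- sqrt((Jxx - Jyy)^2 + 4 * Jxy^2)
  tol <- 1e-12 * max(tr, 0) + 1e-300
  coherency <- matrix(0, nrow(image), ncol(image))
  nz <- tr > tol
  coherency[nz] <- sq[nz] / tr[nz]
  coherency[coherency > 1] <- 1

  ## 0.5 atan2(2 Jxy, Jxx - Jyy) is the dominant *gradient* direction;
  ## structures run perpendicular to it
  theta <- (0.5 * atan2(2 * Jxy, Jxx - Jyy) * 180 / pi + 90) %% 180
  theta[!nz] <- NA_real_

  structure(
    list(theta_deg = theta, coherency = coherency, valid_mask = nz,
         window_sigma_px = window_sigma_px, gradient_method = gradient_method),
    class = "orientation_field"
  )
}

#' @export
print.orientation_field <- function(x, ...) {
  cat(sprintf(
    "<orientation_field: %d x %d px, sigma %g px (%s), %.1f%% valid>\n",
    nrow(x$theta_deg), ncol(x$theta_deg), x$window_sigma_px,
    x$gradient_method, 100 * mean(x$valid_mask)))
  invisible(x)
}

#' Apply intensity and coherency masks to an orientation field
#'
#' A pixel is kept only if its image intensity is strictly larger than
#' `intensity_frac` times the maximum intensity AND its coherency is
#' strictly larger than `coherency_min`.
#'
#' @param image The image the field was computed from (same shape).
#' @param field An [orientation_field()].
#' @param intensity_frac Intensity threshold as a fraction of max; 0.05.
#' @param coherency_min Coherency threshold; 0.05.
#' @return The field with `valid_mask` updated (and `theta_deg` set to `NA`
#'   outside it).
#' @export
apply_masks <- function(image, field, intensity_frac = 0.05,
                        coherency_min = 0.05) {
  stopifnot(inherits(field, "orientation_field"),
            all(dim(image) == dim(field$theta_deg)))
  mask <- (image > intensity_frac * max(image)) &
    (field$coherency > coherency_min) & field$valid_mask
  field$valid_mask <- mask
  field$theta_deg[!mask] <- NA_real_
  field
}

#' Axis naming convention for quadrant labels
#'
#' @param craniocaudal Which matrix axis runs craniocaudally: `"rows"`
#'   (default) or `"cols"`.
#' @param cranial Where the cranial side sits along that axis: `"first"`
#'   (low indices, default) or `"last"`.
#' @param dorsal Where the dorsal side sits along the other
#'   (dorsoventral) axis: `"first"` (default) or `"last"`.
#' @return A list of class `axis_convention`.
#' @export
axis_convention <- function(craniocaudal = c("rows", "cols"),
                            cranial = c("first", "last"),
                            dorsal = c("first", "last")) {
  structure(list(craniocaudal = match.arg(craniocaudal),
                 cranial = match.arg(cranial), dorsal = match.arg(dorsal)),
            class = "axis_convention")
}

#' Split a rectangular ROI into four anatomical quadrants
#'
#' Midpoint split along both axes into cranial/caudal x dorsal/ventral
#' sub-regions. For odd dimensions the extra pixel goes to the
#' caudal/ventral half. Flipping a polarity in the convention swaps the
#' corresponding labels only.
#'
#' @param roi Either `c(nrow, ncol)` for a full image or a list with
#'   integer ranges `rows = c(first, last)`, `cols = c(first, last)`.
#' @param convention An [axis_convention()].
#' @return Tibble of class `quadrant_partition` with columns `quadrant`,
#'   `row_min`, `row_max`, `col_min`, `col_max`.
#' @examples
#' split_quadrants(c(100, 80))
#' @export
split_quadrants <- function(roi, convention = axis_convention()) {
  if (is.numeric(roi) && length(roi) == 2) {
    roi <- list(rows = c(1L, as.integer(roi[1])),
                cols = c(1L, as.integer(roi[2])))
  }
  r0 <- roi$rows[1]; r1 <- roi$rows[2]
  c0 <- roi$cols[1]; c1 <- roi$cols[2]
  nr <- r1 - r0 + 1L; nc <- c1 - c0 + 1L
  if (nr < 2 || nc < 2) {
    abort("ROI must be at least 2 x 2.", class = "ivdmech_error_data")
  }
  ## first half gets floor(n/2); the extra pixel goes to the second half
  rsplit <- r0 + nr %/% 2L - 1L
  csplit <- c0 + nc %/% 2L - 1L
  halves_r <- list(first = c(r0, rsplit), second = c(rsplit + 1L, r1))
  halves_c <- list(first = c(c0, csplit), second = c(csplit + 1L, c1))

  ## caudal and ventral take the larger (second) half by the tie-break,
  ## so cranial/dorsal sit in whichever half the convention names -- but
  ## the tie-break is positional: the extra pixel is in the second half.
  cranial_half <- if (convention$cranial == "first") "first" else "second"
  dorsal_half <- if (convention$dorsal == "first") "first" else "second"
  other <- function(h) if (h == "first") "second" else "first"

  if (convention$craniocaudal == "rows") {
    rows_of <- list(cranial = halves_r[[cranial_half]],
                    caudal = halves_r[[other(cranial_half)]])
    cols_of <- list(dorsal = halves_c[[dorsal_half]],
                    ventral = halves_c[[other(dorsal_half)]])
    get_box <- function(cc, dv) c(rows_of[[cc]], cols_of[[dv]])
  } else {
    cols_of <- list(cranial = halves_c[[cranial_half]],
                    caudal = halves_c[[other(cranial_half)]])
    rows_of <- list(dorsal = halves_r[[dorsal_half]],
                    ventral = halves_r[[other(dorsal_half)]])
    get_box <- function(cc, dv) c(rows_of[[dv]], cols_of[[cc]])
  }

  labs <- expand.grid(cc = c("cranial", "caudal"),
                      dv = c("dorsal", "ventral"),
                      stringsAsFactors = FALSE)
  out <- purrr::pmap(labs, function(cc, dv) {
    b <- get_box(cc, dv)
    tibble(quadrant = paste(cc, dv, sep = "-"),
           row_min = b[1], row_max = b[2], col_min = b[3], col_max = b[4])
  }) |> purrr::list_rbind()
  structure(out, convention = convention,
            class = c("quadrant_partition", class(out)))
}

#' Circular summaries of an orientation field per quadrant
#'
#' @param field A masked [orientation_field()].
#' @param partition A [split_quadrants()] partition.
#' @param n_bins Histogram bins over `[0, 180)`.
#' @param predominant_min_r Resultant-length threshold below which a region
#'   is flagged as having no predominant orientation.
#' @return Tibble: one row per quadrant with `n_pixels`,
#'   `circular_mean_deg`, `circular_dispersion_deg`, `resultant_length`,
#'   `predominant`.
#' @export
quadrant_summaries <- function(field, partition, n_bins = 36,
                               predominant_min_r = 0.1) {
  stopifnot(inherits(field, "orientation_field"),
            inherits(partition, "quadrant_partition"))
  purrr::pmap(partition, function(quadrant, row_min, row_max, col_min,
                                  col_max) {
    th <- field$theta_deg[row_min:row_max, col_min:col_max]
    th <- th[!is.na(th)]
    if (!length(th)) {
      return(tibble(quadrant = quadrant, n_pixels = 0L,
                    circular_mean_deg = NA_real_,
                    circular_dispersion_deg = NA_real_,
                    resultant_length = NA_real_, predominant = FALSE))
    }
    s <- circular_summary(th, n_bins = n_bins,
                          predominant_min_r = predominant_min_r)
    dplyr::bind_cols(tibble(quadrant = quadrant), glance(s))
  }) |> purrr::list_rbind()
}
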