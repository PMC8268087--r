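# File I/O: indentation CSV with JSON sidecar, grayscale TIFF.

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Write an indentation record to CSV (+ JSON sidecar)
#'
#' Columns `time_s`, `displacement_um`, `force_uN`. The sidecar stores tip
#' radius, Poisson's ratio, spring constant, metadata and any generator
#' ground truth.
#'
#' @param record An [indent_record()].
#' @param path Output CSV path.
#' @param sidecar Write the JSON sidecar next to the CSV?
#' @return `path`, invisibly.
#' @export
write_indent_csv <- function(record, path, sidecar = TRUE) {
  stopifnot(inherits(record, "indent_record"))
  readr::write_csv(as_tibble(record)[c("time_s", "displacement_um",
                                       "force_uN")], path)
  if (sidecar) {
    gt <- record_attr(record, "ground_truth")
    side <- list(
      tip_radius_um = record_attr(record, "tip_radius_um"),
      poisson_ratio = record_attr(record, "poisson_ratio"),
      spring_constant_N_m = record_attr(record, "spring_constant_N_m"),
      meta = record_attr(record, "meta")
    )
    if (!is.null(gt)) {
      side$ground_truth <- list(
        E0_kPa = gt$params$E0_kPa, E1_kPa = gt$params$E1_kPa,
        tau1_s = gt$params$tau1_s, contact_index = gt$contact_index)
    }
    jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Read an indentation record from CSV (+ optional JSON sidecar)
#'
#' Requires columns `time_s`, `displacement_um`, `force_uN`; a sidecar JSON
#' (same basename, `.json`) supplies tip radius, Poisson's ratio and
#' specimen metadata when present. Handles LF and CRLF line endings alike.
#'
#' @param path CSV path.
#' @return An [indent_record()].
#' @export
read_indent_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  need <- c("time_s", "displacement_um", "force_uN")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    abort(sprintf("Missing required column(s): %s.",
                  paste(missing, collapse = ", ")),
          class = "ivdmech_error_schema")
  }
  if (any(diff(df$time_s) <= 0)) {
    abort("time_s must be strictly increasing.", class = "ivdmech_error_data")
  }
  side <- list()
  sp <- sidecar_path(path)
  if (file.exists(sp)) side <- jsonlite::read_json(sp, simplifyVector = TRUE)
  gt <- NULL
  if (!is.null(side$ground_truth)) {
    g <- side$ground_truth
    gt <- list(params = sls_params(g$E0_kPa, g$E1_kPa, g$tau1_s),
               contact_index = g$contact_index)
  }
  indent_record(
    df$time_s, df$displacement_um, df$force_uN,
    tip_radius_um = side$tip_radius_um %||% 42,
    poisson_ratio = side$poisson_ratio %||% 0.5,
    spring_constant_N_m = side$spring_constant_N_m %||% 0.48,
    meta = side$meta %||% list(), ground_truth = gt
  )
}

#' Write a grayscale image as 16-bit TIFF (+ JSON sidecar)
#'
#' The image is scaled by its maximum to `[0, 1]` for storage; the scale
#' and any ground-truth fibre angles are recorded in the sidecar.
#'
#' @param image Numeric matrix, or a [generate_fiber_image()] result (whose
#'   ground truth is then written to the sidecar).
#' @param path Output TIFF path.
#' @param sidecar Write the JSON sidecar?
#' @return `path`, invisibly.
#' @export
write_gray_tiff <- function(image, path, sidecar = TRUE) {
  angles <- NULL
  if (inherits(image, "fiber_image")) {
    angles <- image$angles
    image <- image$image
  }
  scale <- max(image, 1e-12)
  tiff::writeTIFF(pmin(pmax(image / scale, 0), 1), path,
                  bits.per.sample = 16)
  if (sidecar) {
    side <- list(intensity_scale = scale)
    if (!is.null(angles)) side$ground_truth_angles = angles
    jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Read a grayscale TIFF (single page or stack)
#'
#' Multi-page files are returned as a list of matrices suitable for
#' [max_project()]; single pages as one matrix. RGB pages are averaged to
#' grayscale.
#'
#' @param path TIFF path.
#' @return Matrix or list of matrices with values in `[0, 1]` times any
#'   sidecar `intensity_scale`.
#' @export
read_gray_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  scale <- 1
  sp <- sidecar_path(path)
  if (file.exists(sp)) {
    side <- jsonlite::read_json(sp, simplifyVector = TRUE)
    scale <- side$intensity_scale %||% 1
  }
  to_gray <- function(p) {
    if (length(dim(p)) == 3) p <- apply(p, c(1, 2), mean)
    p * scale
  }
  pages <- lapply(pages, to_gray)
  if (length(pages) == 1) pages[[1]] else pages
}
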