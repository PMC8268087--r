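# End-to-end pipeline: simulate -> fit -> exclude -> compare, and
# phantom -> orientation -> quadrants -> group table.

#' Build a pipeline configuration
#'
#' All parameters of the end-to-end run in one validated list. Values can
#' also be loaded from a YAML file with [read_pipeline_config()]; unset
#' keys fall back to these defaults.
#'
#' @param output_dir Directory for all outputs (created if needed).
#' @param seed Integer seed governing the whole run.
#' @param curves_dir Optional directory of existing indentation CSVs to fit
#'   instead of (or in addition to) simulated ones.
#' @param simulate Simulate an indentation cohort?
#' @param cohort A [cohort_spec()]; defaults to [cervical_cohort_spec()].
#' @param noise_sd_uN,sample_rate_hz,baseline_duration_s Curve-generation
#'   settings.
#' @param section_thickness_um Section thickness for the substrate check.
#' @param exclusion_k Outlier-exclusion SD multiplier.
#' @param orientation Run the image-orientation arm?
#' @param n_images_per_group Phantom images per group.
#' @param image_size_px Phantom edge length (square images).
#' @param n_fibers Fibres per phantom.
#' @param quadrant_angles Named list `control` / `mdg`, each a data frame
#'   with `quadrant`, `angle_mean_deg`, `angle_sd_deg`.
#' @param window_sigma_px,intensity_frac,coherency_min Orientation-analysis
#'   settings.
#' @param log_level One of `"DEBUG"`, `"INFO"`, `"WARN"`, `"ERROR"`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(output_dir = tempfile("ivdmech_run_"),
                            seed = 1L,
                            curves_dir = NULL,
                            simulate = TRUE,
                            cohort = cervical_cohort_spec(),
                            noise_sd_uN = 0.001,
                            sample_rate_hz = 100,
                            baseline_duration_s = 1,
                            section_thickness_um = 25,
                            exclusion_k = 3,
                            orientation = TRUE,
                            n_images_per_group = 3,
                            image_size_px = 256,
                            n_fibers = 120,
                            quadrant_angles = default_quadrant_angles(),
                            window_sigma_px = 10,
                            intensity_frac = 0.05,
                            coherency_min = 0.05,
                            log_level = "INFO") {
  cfg <- list(output_dir = output_dir, seed = as.integer(seed),
              curves_dir = curves_dir, simulate = simulate, cohort = cohort,
              noise_sd_uN = noise_sd_uN, sample_rate_hz = sample_rate_hz,
              baseline_duration_s = baseline_duration_s,
              section_thickness_um = section_thickness_um,
              exclusion_k = exclusion_k, orientation = orientation,
              n_images_per_group = n_images_per_group,
              image_size_px = image_size_px, n_fibers = n_fibers,
              quadrant_angles = quadrant_angles,
              window_sigma_px = window_sigma_px,
              intensity_frac = intensity_frac,
              coherency_min = coherency_min, log_level = log_level)
  if (!cfg$log_level %in% c("DEBUG", "INFO", "WARN", "ERROR")) {
    abort("log_level must be DEBUG/INFO/WARN/ERROR.",
          class = "ivdmech_error_invalid_spec")
  }
  structure(cfg, class = "pipeline_config")
}

#' Default per-quadrant phantom orientations
#'
#' Inner annulus fibrosus collagen-II orientations (degrees from the
#' dorsoventral axis) per quadrant for control and mdg groups at TS24:
#' control fibres run craniocaudally in the caudal-ventral quadrant
#' (87 deg) whereas mdg fibres run dorsoventrally there (7 deg).
#'
#' @return Named list of two tibbles (`control`, `mdg`).
#' @export
default_quadrant_angles <- function() {
  quads <- c("cranial-dorsal", "caudal-dorsal", "cranial-ventral",
             "caudal-ventral")
  list(
    control = tibble(quadrant = quads,
                     angle_mean_deg = c(93, 90, 104, 87),
                     angle_sd_deg = c(5, 5, 15, 7)),
    mdg = tibble(quadrant = quads,
                 angle_mean_deg = c(95, 107, 129, 7),
                 angle_sd_deg = c(8, 6, 10, 7))
  )
}

#' Load a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; unknown keys are
#' rejected. `quadrant_angles` may be given as nested lists of records.
#'
#' @param path YAML file.
#' @param ... Overrides applied after the file is read (CLI flags).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  raw <- yaml::read_yaml(path)
  over <- list(...)
  raw[names(over)] <- over
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    abort(sprintf("Unknown config key(s): %s.",
                  paste(unknown, collapse = ", ")),
          class = "ivdmech_error_invalid_spec")
  }
  if (!is.null(raw$quadrant_angles)) {
    raw$quadrant_angles <- lapply(raw$quadrant_angles, function(g) {
      as_tibble(do.call(rbind.data.frame, g))
    })
  }
  if (!is.null(raw$cohort)) {
    raw$cohort <- do.call(cohort_spec, as.list(
      as_tibble(do.call(rbind.data.frame, raw$cohort))))
  }
  do.call(pipeline_config, raw)
}

pipe_log <- function(cfg, level, fmt, ...) {
  ranks <- c(DEBUG = 1, INFO = 2, WARN = 3, ERROR = 4)
  if (ranks[[level]] >= ranks[[cfg$log_level]]) {
    message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
  }
}

#' Run the full analysis pipeline
#'
#' Indentation arm: simulate a cohort (and/or read curves from
#' `curves_dir`), detect contact and fit each indent, apply validity
#' checks, exclude three-SD outliers, and compare groups per structure and
#' metric. Orientation arm: generate per-group phantoms, compute masked
#' orientation fields, summarize quadrants per image, and aggregate an
#' across-sample orientation table. Writes `fits.csv`,
#' `group_comparison.csv`, `orientation_quadrants.csv`,
#' `orientation_table.csv` and a `manifest.json` (config hash, seed,
#' package version, outputs, failure count) under `output_dir`.
#' Per-item failures are logged and counted; the run continues.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `fits`, `comparison`, `quadrants`,
#'   `orientation_table`, `n_failures`, `manifest_path`, `output_files`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  n_failures <- 0L
  outputs <- character()

  records <- list()
  meta_rows <- list()
  if (isTRUE(config$simulate)) {
    pipe_log(config, "INFO", "simulating cohort (seed %d)", config$seed)
    cohort <- generate_cohort(config$cohort, seed = config$seed,
                              noise_sd_uN = config$noise_sd_uN,
                              sample_rate_hz = config$sample_rate_hz,
                              baseline_duration_s = config$baseline_duration_s)
    records <- cohort$record
    meta_rows <- purrr::pmap(
      dplyr::select(cohort, "group", "specimen", "structure", "level",
                    "stage", "indent"), list)
  }
  if (!is.null(config$curves_dir)) {
    files <- sort(list.files(config$curves_dir, pattern = "\\.csv$",
                             full.names = TRUE))
    for (f in files) {
      rec <- tryCatch(read_indent_csv(f), error = function(e) {
        pipe_log(config, "ERROR", "failed to read %s: %s", f,
                 conditionMessage(e))
        NULL
      })
      if (is.null(rec)) { n_failures <- n_failures + 1L; next }
      m <- record_attr(rec, "meta")
      records <- c(records, list(rec))
      meta_rows <- c(meta_rows, list(list(
        group = m$group %||% NA_character_,
        specimen = m$specimen %||% basename(f),
        structure = m$structure %||% NA_character_,
        level = m$level %||% NA_character_,
        stage = m$stage %||% NA_character_, indent = NA_integer_)))
    }
  }

  fits <- NULL
  comparison <- NULL
  if (length(records)) {
    fit_rows <- purrr::imap(records, function(rec, i) {
      m <- meta_rows[[i]]
      row <- tryCatch({
        ft <- fit_sls(rec)
        val <- check_validity(max(rec$displacement_um),
                              record_attr(rec, "tip_radius_um"),
                              config$section_thickness_um)
        pipe_log(config, "DEBUG", "indent %d: E_ins %.3g kPa f %.3f", i,
                 ft$E_ins_kPa, ft$f)
        dplyr::bind_cols(as_tibble(m),
                         tibble(E_ins_kPa = ft$E_ins_kPa, f = ft$f,
                                tau1_s = ft$params$tau1_s,
                                rmse_uN = ft$rmse_uN,
                                converged = ft$converged),
                         val)
      }, error = function(e) {
        pipe_log(config, "ERROR", "indent %d failed: %s", i,
                 conditionMessage(e))
        NULL
      })
      if (is.null(row)) n_failures <<- n_failures + 1L
      row
    })
    fits <- purrr::list_rbind(purrr::compact(fit_rows))
    fp <- file.path(config$output_dir, "fits.csv")
    readr::write_csv(fits, fp); outputs <- c(outputs, fp)

    usable <- dplyr::filter(fits, .data$converged, .data$strain_ok,
                            .data$substrate_ok)
    comparison <- tryCatch(
      comparison_table(usable, k = config$exclusion_k),
      error = function(e) {
        pipe_log(config, "ERROR", "group comparison failed: %s",
                 conditionMessage(e))
        n_failures <<- n_failures + 1L
        NULL
      })
    if (!is.null(comparison)) {
      cp <- file.path(config$output_dir, "group_comparison.csv")
      readr::write_csv(comparison, cp); outputs <- c(outputs, cp)
    }
  }

  quadrants <- NULL
  orientation_table <- NULL
  if (isTRUE(config$orientation)) {
    qrows <- list()
    groups <- names(config$quadrant_angles)
    for (gi in seq_along(groups)) {
      g <- groups[gi]
      for (s in seq_len(config$n_images_per_group)) {
        res <- tryCatch({
          fim <- generate_fiber_image(fiber_image_spec(
            width_px = config$image_size_px,
            height_px = config$image_size_px,
            n_fibers = config$n_fibers,
            quadrants = config$quadrant_angles[[g]],
            seed = config$seed * 1000L + gi * 100L + s))
          fld <- orientation_field(fim$image,
                                   window_sigma_px = config$window_sigma_px)
          fld <- apply_masks(fim$image, fld,
                             intensity_frac = config$intensity_frac,
                             coherency_min = config$coherency_min)
          part <- split_quadrants(dim(fim$image))
          qs <- quadrant_summaries(fld, part)
          pipe_log(config, "INFO", "image %s/%d: %d quadrants summarized",
                   g, s, nrow(qs))
          dplyr::mutate(qs, group = g, sample = s, .before = 1)
        }, error = function(e) {
          pipe_log(config, "ERROR", "image %s/%d failed: %s", g, s,
                   conditionMessage(e))
          NULL
        })
        if (is.null(res)) n_failures <- n_failures + 1L
        qrows <- c(qrows, list(res))
      }
    }
    quadrants <- purrr::list_rbind(purrr::compact(qrows))
    if (!is.null(quadrants) && nrow(quadrants)) {
      qp <- file.path(config$output_dir, "orientation_quadrants.csv")
      readr::write_csv(quadrants, qp); outputs <- c(outputs, qp)
      orientation_table <- group_orientation_table(
        quadrants, by = c("group", "quadrant"))
      op <- file.path(config$output_dir, "orientation_table.csv")
      readr::write_csv(orientation_table, op); outputs <- c(outputs, op)
    }
  }

  manifest <- list(
    config_hash = rlang::hash(unclass(config)),
    seed = config$seed,
    package_version = as.character(packageVersion("ivdmech")),
    n_failures = n_failures,
    outputs = basename(outputs)
  )
  mp <- file.path(config$output_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE)

  pipe_log(config, "INFO", "pipeline done: %d failure(s)", n_failures)
  invisible(list(fits = fits, comparison = comparison, quadrants = quadrants,
                 orientation_table = orientation_table,
                 n_failures = n_failures, manifest_path = mp,
                 output_files = outputs))
}
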