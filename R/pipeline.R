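#' Run configuration
#'
#' Assembles and validates the configuration for one reproducible pipeline
#' run: the stage mode, output directory, detector settings, a seed recorded
#' in every output, and stage parameters. Can be loaded from a YAML file with
#' the same field names.
#'
#' @param mode One of `"simulate"`, `"preprocess"`, `"stp"`, `"esfr"`,
#'   `"stretch"`, `"full"`.
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed for every stochastic stage.
#' @param detector A [detector_config()] or a list of its arguments.
#' @param preset Simulation preset for `mode = "simulate"`: `"stp"`,
#'   `"edge"` or `"stretch"`.
#' @param paths Named list of required input paths (e.g. `raw`, `flat`,
#'   `dark` for `mode = "preprocess"`); each must exist at run start.
#' @param params Named list of stage parameters (`oversample`, `n_bins`,
#'   `n_zones`, `exposure_times_ms`, `dose_rate`, `elongations_pct`, ...).
#' @return An object of class `run_config`.
#' @export
run_config <- function(mode = c("full", "simulate", "preprocess", "stp",
                                "esfr", "stretch"),
                       out_dir, seed = 1L, detector = detector_config(),
                       preset = c("stp", "edge", "stretch"),
                       paths = list(), params = list()) {
  mode <- match.arg(mode)
  preset <- match.arg(preset)
  if (missing(out_dir)) stop("`out_dir` is required", call. = FALSE)
  if (!inherits(detector, "detector_config"))
    detector <- do.call(detector_config, detector)
  for (nm in names(paths))
    if (!file.exists(paths[[nm]]))
      stop(sprintf("input path `%s` does not exist: %s", nm, paths[[nm]]),
           call. = FALSE)
  defaults <- list(oversample = 4, n_bins = 256, n_zones = 3,
                   exposure_times_ms = c(20, 50, 100, 150, 200, 300, 400, 500),
                   dose_rate = 2, edge_angle_deg = 4.5, psf_sigma_mm = 0.2,
                   elongations_pct = seq(0, 100, by = 20),
                   shape_px = c(256, 256))
  params <- utils::modifyList(defaults, params)
  structure(list(mode = mode, out_dir = out_dir, seed = as.integer(seed),
                 detector = detector, preset = preset, paths = paths,
                 params = params),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' @param path YAML file whose top-level fields mirror [run_config()]
#'   arguments.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

# Stable content hash of an R object (used for config identity in manifests).
.config_hash <- function(x) {
  raw <- serialize(x, connection = NULL, version = 2)
  # tools::md5sum works on files only; route through a temp file
  tf <- tempfile()
  on.exit(unlink(tf))
  writeBin(raw, tf)
  unname(tools::md5sum(tf))
}

#' Execute a configured pipeline run
#'
#' Runs the requested stages in dependency order and writes a manifest JSON
#' (`manifest.json` in `out_dir`) listing every output file with its MD5
#' checksum, the configuration hash and the seed. The same configuration and
#' seed produce identical manifest contents; stage timings and validation
#' warnings go to the log, not the manifest.
#'
#' @param config A [run_config()].
#' @param quiet Suppress log messages.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_msg <- function(...) if (!quiet) message(sprintf(...))
  outputs <- character(0)
  warnings <- character(0)
  add_output <- function(path) outputs <<- c(outputs, path)
  p <- config$params
  det <- config$detector

  t0 <- proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    s <- proc.time()[["elapsed"]]
    force(expr)
    log_msg("[%s] done in %.1f s", name, proc.time()[["elapsed"]] - s)
  }

  scene_default <- function(margin = 16)
    synthetic_scene(shape_px = p$shape_px,
                    skin_polygon = rect_polygon(p$shape_px[1], p$shape_px[2],
                                                margin = margin))

  # margin leaving room for the largest elongation of the stretch preset
  stretch_margin <- function() {
    lambda_max <- 1 + max(p$elongations_pct) / 100
    s <- min(p$shape_px)
    ceiling(s / 2 - (s / 2 - 2) / lambda_max) + 0.5
  }

  sim_dir <- file.path(config$out_dir, "stacks")

  simulate_preset <- function(preset) {
    dir.create(sim_dir, recursive = TRUE, showWarnings = FALSE)
    if (preset == "stp") {
      series <- make_stp_series(scene_default(), det, p$exposure_times_ms,
                                p$dose_rate, seed = config$seed)
      for (i in seq_along(series$points)) {
        f <- file.path(sim_dir, sprintf("stp_%03d.tif", i))
        write_frame_stack(series$points[[i]]$stack, f); add_output(f)
        add_output(paste0(f, ".json"))
      }
      for (lbl in c("flat", "dark")) {
        f <- file.path(sim_dir, paste0(lbl, ".tif"))
        write_frame_stack(series[[lbl]], f); add_output(f)
        add_output(paste0(f, ".json"))
      }
      series
    } else if (preset == "edge") {
      sc <- make_slanted_edge_scene(p$edge_angle_deg, p$psf_sigma_mm,
                                    config = det, shape_px = p$shape_px)
      stack <- make_frame_stack(sc, det, p$dose_rate * det$exposure_ms / 1000,
                                seed = config$seed)
      dark <- make_frame_stack(sc, det, 0, seed = config$seed + 1L,
                               label = "dark")
      for (nm in c("edge", "edge_dark")) {
        f <- file.path(sim_dir, paste0(nm, ".tif"))
        write_frame_stack(if (nm == "edge") stack else dark, f)
        add_output(f); add_output(paste0(f, ".json"))
      }
      list(stack = stack, dark = dark, scene = sc)
    } else {
      series <- make_stretch_series(scene_default(margin = stretch_margin()), p$elongations_pct,
                                    config = det, seed = config$seed)
      for (i in seq_along(series)) {
        f <- file.path(sim_dir, sprintf("stretch_%03d.tif", i))
        write_frame_stack(series[[i]]$stack, f); add_output(f)
        add_output(paste0(f, ".json"))
      }
      series
    }
  }

  results <- list()
  if (config$mode %in% c("simulate")) {
    stage("simulate", results$sim <- simulate_preset(config$preset))
  }
  if (config$mode == "preprocess") {
    for (nm in c("raw", "flat", "dark"))
      if (is.null(config$paths[[nm]]))
        stop(sprintf("mode 'preprocess' needs input path `%s`", nm),
             call. = FALSE)
    stage("preprocess", {
      raw <- average_frames(read_frame_stack(config$paths$raw))
      flat <- average_frames(read_frame_stack(config$paths$flat))
      dark <- average_frames(read_frame_stack(config$paths$dark))
      roi <- detect_skin_roi(flat, dark, full_scale = det$full_scale)
      corr <- flat_field_correct(raw, dark, flat, roi)
      f <- file.path(config$out_dir, "corrected.tif")
      px <- corr$pixels
      px[!roi$mask] <- 0
      tiff::writeTIFF(px / max(px), f, bits.per.sample = 32L)
      add_output(f)
      jsonlite::write_json(list(m = corr$m, scale = max(px)),
                           file.path(config$out_dir, "corrected_meta.json"),
                           auto_unbox = TRUE, digits = NA)
      add_output(file.path(config$out_dir, "corrected_meta.json"))
      fc <- file.path(config$out_dir, "roi_contour.csv")
      utils::write.csv(as.data.frame(roi$contour), fc, row.names = FALSE)
      add_output(fc)
      results$corrected <- corr
    })
  }
  if (config$mode %in% c("stp", "full")) {
    stage("stp", {
      series <- results$sim_stp <- {
        series <- make_stp_series(scene_default(), det, p$exposure_times_ms,
                                  p$dose_rate, seed = config$seed)
      }
      ana <- stp_analysis(series)
      f1 <- file.path(config$out_dir, "stp_points.csv")
      utils::write.csv(ana$points, f1, row.names = FALSE); add_output(f1)
      f2 <- file.path(config$out_dir, "stp_fit.json")
      jsonlite::write_json(ana$fit[c("slope", "intercept", "r_squared",
                                     "max_relative_deviation", "is_linear")],
                           f2, auto_unbox = TRUE, digits = NA)
      add_output(f2)
      results$stp <- ana
    })
  }
  if (config$mode %in% c("esfr", "full")) {
    stage("esfr", {
      sc <- make_slanted_edge_scene(p$edge_angle_deg, p$psf_sigma_mm,
                                    config = det, shape_px = p$shape_px)
      stack <- make_frame_stack(sc, det, p$dose_rate * det$exposure_ms / 1000,
                                seed = config$seed + 10L)
      m <- average_frames(stack) - sc$response_offset
      margin <- 24L
      sub <- m[(margin + 1):(p$shape_px[1] - margin),
               (margin + 1):(p$shape_px[2] - margin)]
      curve <- esfr_analysis(edge_roi(sub, pitch_mm = det$pixel_pitch_mm),
                             oversample = p$oversample)
      if (!curve$validation$valid)
        warnings <- c(warnings, curve$validation$reasons)
      f1 <- file.path(config$out_dir, "sfr_curve.csv")
      utils::write.csv(data.frame(frequency_lp_mm = curve$frequency_lp_mm,
                                  sfr = curve$value),
                       f1, row.names = FALSE); add_output(f1)
      f2 <- file.path(config$out_dir, "sfr_summary.json")
      jsonlite::write_json(list(sfr50 = curve$sfr50, sfr10 = curve$sfr10,
                                angle_deg = curve$edge_angle_deg),
                           f2, auto_unbox = TRUE, digits = NA)
      add_output(f2)
      results$esfr <- curve
    })
  }
  if (config$mode %in% c("stretch", "full")) {
    stage("stretch", {
      series <- make_stretch_series(scene_default(margin = stretch_margin()),
                                    p$elongations_pct,
                                    config = det, seed = config$seed + 20L)
      ana <- stretch_analysis(series)
      f1 <- file.path(config$out_dir, "stretch_table.csv")
      utils::write.csv(ana$table, f1, row.names = FALSE); add_output(f1)
      f2 <- file.path(config$out_dir, "stretch_trends.json")
      jsonlite::write_json(ana$mpv_trend[c("slope", "intercept",
                                           "r_squared")],
                           f2, auto_unbox = TRUE, digits = NA)
      add_output(f2)
      results$stretch <- ana
    })
  }

  manifest <- list(
    # hash the scientific configuration, not the output location
    config_hash = .config_hash(unclass(config)[c("mode", "seed", "detector",
                                                 "preset", "params")]),
    seed = config$seed,
    mode = config$mode,
    outputs = lapply(stats::setNames(outputs, basename(outputs)),
                     function(f) list(path = f,
                                      md5 = unname(tools::md5sum(f)))),
    warnings = warnings
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  log_msg("[pipeline] completed in %.1f s",
          proc.time()[["elapsed"]] - t0)
  invisible(manifest)
}
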