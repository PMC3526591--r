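# File formats, run configuration and the end-to-end pipeline.

#' Read cell trajectories from CSV
#'
#' Long format: one row per cell per frame, columns `cell_id`, `t_min`,
#' `x_um`, `y_um`, and optionally `z_um`, `diameter_um`. Malformed rows
#' (non-numeric coordinates) are reported with their line numbers;
#' non-monotone time or duplicate time points are reported with the
#' offending cell id. A file holding only the header yields an empty
#' track set with a warning.
#'
#' @param path CSV path.
#' @param ... Passed to [track_set()] (`t_stimulus`, `gradient_dir`, ...).
#' @return A [track_set()].
#' @export
read_tracks <- function(path, ...) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "t_min", "x_um", "y_um")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("'%s' is missing required column(s): %s", path,
                 paste(miss, collapse = ", ")))
  if (!nrow(df)) {
    warning(sprintf("'%s' holds no data rows; returning an empty track set",
                    path))
    return(track_set(df, ...))
  }
  num_cols <- intersect(c("t_min", "x_um", "y_um", "z_um", "diameter_um"),
                        names(df))
  for (cl in num_cols) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- which(is.na(v) & !is.na(df[[cl]]))
    if (length(bad))
      stop(sprintf("'%s': non-numeric %s on line(s) %s", path, cl,
                   paste(bad + 1L, collapse = ", ")))  # +1 for the header
    df[[cl]] <- v
  }
  track_set(df, ...)
}

#' Write cell trajectories to CSV
#'
#' Inverse of [read_tracks()]: writing then reading reproduces the track
#' data frame value-for-value.
#'
#' @param tracks A [track_set()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  stopifnot(inherits(tracks, "track_set"))
  utils::write.csv(tracks$tracks, path, row.names = FALSE)
  invisible(path)
}

#' Write a concentration field as long-format CSV
#'
#' Columns `y_mm`, `t_s`, `c_norm`; loadable by [read_field_csv()].
#'
#' @param field A `concentration_field`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_field_csv <- function(field, path) {
  stopifnot(inherits(field, "concentration_field"))
  df <- data.frame(y_mm = rep(field$y_mm, times = length(field$t_s)),
                   t_s = rep(field$t_s, each = length(field$y_mm)),
                   c_norm = as.vector(field$C_norm))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a long-format concentration field CSV
#'
#' @param path CSV with columns `y_mm`, `t_s`, `c_norm` on a full grid.
#' @return A `concentration_field` (grid reconstructed from the unique
#'   coordinates; geometry/parameters unset).
#' @export
read_field_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("y_mm", "t_s", "c_norm") %in% names(df)))
    stop(sprintf("'%s' must have columns y_mm, t_s, c_norm", path))
  y <- sort(unique(df$y_mm)); t <- sort(unique(df$t_s))
  if (nrow(df) != length(y) * length(t))
    stop(sprintf("'%s' is not a full y x t grid", path))
  df <- df[order(df$t_s, df$y_mm), ]
  structure(list(y_mm = y, t_s = t,
                 C_norm = matrix(df$c_norm, length(y), length(t)),
                 mass = NULL, geometry = NULL, params = NULL),
            class = "concentration_field")
}

.config_defaults <- function() list(
  # diffusion / chamber
  D_cm2_s = 2e-6, C0 = 50, L_reservoir_mm = 20, L_membrane_mm = 0.15,
  L_gel_mm = 5, D_factor_membrane = 1, dy_mm = 0.05, dt_s = 10,
  t_end_s = 7200,
  # experiment / statistics
  t_stimulus_min = 30, gradient_dir = c(0, -1, 0), frame_interval_min = 1,
  projection = "xy", bin_min = 5, motile_window_min = 10, alpha = 0.05,
  # tracks: either a CSV to analyse or a synthetic profile to generate
  tracks_csv = NULL, profile = "donorA-like",
  # fluorescence stage
  calibration_slope = 2, calibration_intercept = 10, gray_noise_sd = 1,
  positions_mm = c(2, 3, 4, 5),
  # run
  seed = 1, out_dir = "gradchamber_report")

#' Read and validate a run configuration
#'
#' JSON configuration for [run_full_pipeline()]. Unknown keys are
#' rejected with a message naming them; known keys override the
#' defaults, which are returned for keys the file omits.
#'
#' @param path JSON file path, or `NULL` for pure defaults.
#' @param overrides Named list applied after the file (e.g. a seed).
#' @return Object of class `run_config` (a named list).
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- .config_defaults()
  user <- if (!is.null(path)) jsonlite::fromJSON(path) else list()
  user <- utils::modifyList(user, overrides)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(cfg, user)
  stopifnot(cfg$projection %in% c("xy", "xyz"),
            cfg$alpha > 0, cfg$alpha < 1, cfg$bin_min > 0)
  structure(cfg, class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Stage order mirrors the assay workflow: (1) solve the chamber
#' concentration field; (2) simulate the fluorescence readout through the
#' configured calibration line and re-fit the diffusion coefficient from
#' it; (3) obtain trajectories (from `tracks_csv` if configured,
#' otherwise a synthetic fixture experiment); (4) compute the tidy
#' motility report. Artifacts written under `out_dir`: `field.csv`,
#' `gray_series.csv`, `fit.json`, `tracks.csv`, `truth.json` (synthetic
#' runs only), `motility_report.csv`, `provenance.json`. Every CSV is
#' loadable by the package's own readers, and the run is fully
#' deterministic given the seed (provenance carries no wall-clock time,
#' so identical seeds give checksum-identical outputs). A stage failure
#' aborts with the stage name; artifacts of completed stages remain.
#'
#' @param config A [read_run_config()] object (or `NULL` for defaults).
#' @param out_dir Output directory (default from the config).
#' @return `out_dir`, invisibly.
#' @export
run_full_pipeline <- function(config = NULL, out_dir = NULL) {
  if (is.null(config)) config <- read_run_config()
  stopifnot(inherits(config, "run_config"))
  if (is.null(out_dir)) out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  field <- stage("diffusion", {
    geom <- chamber_geometry(config$L_reservoir_mm, config$L_membrane_mm,
                             config$L_gel_mm, config$D_factor_membrane)
    fld <- solve_chamber_1d(geom, diffusion_params(config$D_cm2_s, config$C0),
                            t_end_s = config$t_end_s, dt_s = config$dt_s,
                            dy_mm = config$dy_mm)
    write_field_csv(fld, file.path(out_dir, "field.csv"))
    fld
  })

  stage("fluorescence", {
    curve <- list(slope = config$calibration_slope,
                  intercept = config$calibration_intercept)
    series <- simulate_gray_series(curve, field,
                                   positions_mm = config$positions_mm,
                                   noise_sd = config$gray_noise_sd,
                                   C0 = config$C0, seed = config$seed)
    utils::write.csv(series, file.path(out_dir, "gray_series.csv"),
                     row.names = FALSE)
    cal_curve <- structure(list(slope = curve$slope,
                                intercept = curve$intercept,
                                r_squared = 1,
                                valid_range = c(0, config$C0)),
                           class = "calibration_curve")
    obs <- gray_series_to_observations(series, cal_curve, config$C0)
    fit <- fit_diffusion_coefficient(obs)
    jsonlite::write_json(
      list(D_cm2_s = fit$D_cm2_s, rmse = fit$rmse, model = fit$model,
           n_obs = fit$n_obs),
      file.path(out_dir, "fit.json"), auto_unbox = TRUE, digits = NA)
  })

  tracks <- stage("tracks", {
    if (!is.null(config$tracks_csv)) {
      read_tracks(config$tracks_csv, t_stimulus = config$t_stimulus_min,
                  gradient_dir = config$gradient_dir,
                  frame_interval = config$frame_interval_min)
    } else {
      exper <- make_fixture_experiment(config$profile, seed = config$seed)
      jsonlite::write_json(
        exper$ground_truth[c("cell_id", "mover_pre", "mover_post",
                             "speed_scale_pre", "speed_scale_post")],
        file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
      exper$tracks
    }
  })
  stage("tracks", write_tracks(tracks, file.path(out_dir, "tracks.csv")))

  stage("statistics", {
    rep <- motility_report(tracks, bin = config$bin_min,
                           motile_window = config$motile_window_min,
                           alpha = config$alpha,
                           projection = config$projection)
    utils::write.csv(rep, file.path(out_dir, "motility_report.csv"),
                     row.names = FALSE)
  })

  stage("provenance", {
    cfg <- unclass(config)
    jsonlite::write_json(
      list(config = cfg, seed = config$seed,
           package_version = as.character(utils::packageVersion("gradchamber")),
           r_version = R.version.string),
      file.path(out_dir, "provenance.json"), auto_unbox = TRUE, digits = NA)
  })

  invisible(out_dir)
}
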