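# File formats: system geometry and calibration as JSON (mm units,
# row-major matrices), feature frames and gaze samples as CSV with
# numbers fixed at 9 significant digits so writer -> reader round trips
# are lossless at the precision the pipeline uses.

fmt9 <- function(x) {
  ifelse(is.na(x), "", sprintf("%.9g", x))
}

mat_rowmajor <- function(m) as.numeric(t(m))
rowmajor_mat <- function(v) matrix(as.numeric(v), 3, 3, byrow = TRUE)

camera_to_list <- function(cam) {
  list(nodal_point = cam$nodal_point, rotation = mat_rowmajor(cam$rotation),
       focal_length = cam$focal_length, principal_point = cam$principal_point,
       sensor_size = cam$sensor_size)
}

camera_from_list <- function(x, field) {
  need <- c("nodal_point", "rotation", "focal_length", "principal_point", "sensor_size")
  miss <- setdiff(need, names(x))
  if (length(miss))
    sg_stop(sprintf("geometry config: %s is missing field(s) %s",
                    field, paste(miss, collapse = ", ")), "stereogaze_config_error")
  R <- rowmajor_mat(x$rotation)
  if (!is_rotation_matrix(R))
    sg_stop(sprintf("geometry config: %s rotation is not orthonormal with det +1", field),
            "stereogaze_config_error")
  camera_model(x$nodal_point, R, x$focal_length, x$principal_point, x$sensor_size)
}

#' Write a system geometry to JSON
#'
#' @param geometry a `system_geometry`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_geometry <- function(geometry, path) {
  obj <- list(camera1 = camera_to_list(geometry$camera1),
              camera2 = camera_to_list(geometry$camera2),
              illuminator1 = geometry$illuminator1,
              illuminator2 = geometry$illuminator2,
              screen_rotation = mat_rowmajor(geometry$screen_rotation),
              screen_translation = geometry$screen_translation,
              screen_resolution = geometry$screen_resolution,
              pixel_pitch = geometry$pixel_pitch)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load and validate a system geometry from JSON
#'
#' Orthonormality of every rotation and positivity of the pixel pitch are
#' checked on load; violations raise a `stereogaze_config_error` naming
#' the offending field.
#'
#' @param path JSON file written by [write_geometry()].
#' @return a `system_geometry`.
#' @export
read_geometry <- function(path) {
  if (!file.exists(path))
    sg_stop(sprintf("geometry file not found: %s", path), "stereogaze_config_error")
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("camera1", "camera2", "illuminator1", "illuminator2",
            "screen_rotation", "screen_translation", "screen_resolution",
            "pixel_pitch")
  miss <- setdiff(need, names(x))
  if (length(miss))
    sg_stop(sprintf("geometry config missing field(s): %s",
                    paste(miss, collapse = ", ")), "stereogaze_config_error")
  Rs <- rowmajor_mat(x$screen_rotation)
  if (!is_rotation_matrix(Rs))
    sg_stop("geometry config: screen_rotation is not orthonormal with det +1",
            "stereogaze_config_error")
  if (!is.numeric(x$pixel_pitch) || x$pixel_pitch <= 0)
    sg_stop("geometry config: pixel_pitch must be positive", "stereogaze_config_error")
  system_geometry(camera_from_list(x$camera1, "camera1"),
                  camera_from_list(x$camera2, "camera2"),
                  x$illuminator1, x$illuminator2,
                  Rs, x$screen_translation, x$screen_resolution, x$pixel_pitch)
}

#' Write a one-point calibration to JSON
#'
#' @param calib a `gaze_calibration`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(calib, path) {
  jsonlite::write_json(unclass(calib), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a one-point calibration from JSON
#'
#' @param path JSON file written by [write_calibration()].
#' @return a `gaze_calibration`.
#' @export
read_calibration <- function(path) {
  if (!file.exists(path))
    sg_stop(sprintf("calibration file not found: %s", path), "stereogaze_config_error")
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!all(c("alpha", "beta", "K") %in% names(x)) || x$K <= 0)
    sg_stop("calibration config must provide alpha, beta and positive K",
            "stereogaze_config_error")
  structure(list(alpha = x$alpha, beta = x$beta, K = x$K,
                 n_samples_used = if (is.null(x$n_samples_used)) NA_integer_
                 else x$n_samples_used),
            class = "gaze_calibration")
}

feature_cols <- c("pupil_x", "pupil_y", "glint1_x", "glint1_y",
                  "glint2_x", "glint2_y")

#' Write feature frames to CSV
#'
#' One row per camera frame per eye; numbers at 9 significant digits.
#'
#' @param frames feature-frame data.frame (`timestamp_s`, `cam`, `eye`,
#'   pixel columns, `valid`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(frames, path) {
  out <- data.frame(timestamp_s = fmt9(frames$timestamp_s),
                    cam = frames$cam, eye = frames$eye)
  for (cc in feature_cols) out[[cc]] <- fmt9(frames[[cc]])
  out$valid <- as.integer(frames$valid)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read feature frames from CSV
#'
#' @param path CSV written by [write_features_csv()] (or the same dialect
#'   from another tool).
#' @return feature-frame data.frame.
#' @export
read_features_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp_s", "cam", "eye", feature_cols, "valid")
  miss <- setdiff(need, names(x))
  if (length(miss))
    sg_stop(sprintf("feature CSV missing column(s): %s", paste(miss, collapse = ", ")),
            "stereogaze_config_error")
  x$valid <- as.logical(x$valid) | x$valid == 1
  for (cc in c("timestamp_s", feature_cols)) x[[cc]] <- as.numeric(x[[cc]])
  x
}

gaze_cols <- c("Cx", "Cy", "Cz", "theta", "phi", "theta_corr", "phi_corr",
               "pog_x_mm", "pog_y_mm", "pogc_x_mm", "pogc_y_mm", "K_actual")

#' Write gaze samples to CSV
#'
#' @param gaze gaze-sample data.frame from [reconstruct_gaze()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gaze_csv <- function(gaze, path) {
  out <- data.frame(timestamp_s = fmt9(gaze$timestamp_s), eye = gaze$eye)
  for (cc in gaze_cols) out[[cc]] <- fmt9(gaze[[cc]])
  out$valid <- as.integer(gaze$valid)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read gaze samples from CSV
#'
#' @param path CSV written by [write_gaze_csv()].
#' @return gaze-sample data.frame.
#' @export
read_gaze_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("timestamp_s", "eye", gaze_cols, "valid"), names(x))
  if (length(miss))
    sg_stop(sprintf("gaze CSV missing column(s): %s", paste(miss, collapse = ", ")),
            "stereogaze_config_error")
  x$valid <- as.logical(x$valid) | x$valid == 1
  for (cc in c("timestamp_s", gaze_cols)) x[[cc]] <- as.numeric(x[[cc]])
  x
}

#' Synthetic validation-study replica
#'
#' Runs the full pipeline on simulated data: a one-point calibration at
#' the central head position, then steady fixations of the target grid at
#' each head position (the central position plus horizontal and vertical
#' bite-board translations), reconstruction, and per-head-position
#' fixation accuracy/precision metrics in degrees. All randomness derives
#' from `seed`; identical seeds give identical reports.
#'
#' @param out_dir output directory for `report.json` (NULL to skip
#'   writing).
#' @param seed integer master seed.
#' @param geometry a `system_geometry`.
#' @param eye an `eye_params` at the nominal central position.
#' @param targets target table (screen mm); defaults to the 54-target
#'   grid.
#' @param head_offsets list of head translations, mm; defaults to the 9
#'   bite-board positions (0/±50 mm horizontal x 0/±30 mm vertical).
#' @param pixel_noise_sd per-frame feature noise, px.
#' @param mode pupil imaging mode for the simulation.
#' @param duration_s per-trial fixation duration, s.
#' @param filter_width median-filter width, samples.
#' @param quiet suppress per-stage log messages.
#' @return the report: a list with the calibration and one block per head
#'   position (`head_offset_mm`, fixation metrics in deg, trial counts).
#' @export
run_demo <- function(out_dir = NULL, seed = 1, geometry = default_rig(),
                     eye = eye_params(), targets = target_grid(),
                     head_offsets = NULL, pixel_noise_sd = 0.1,
                     mode = "no_refraction", duration_s = 0.2,
                     filter_width = 20, quiet = FALSE) {
  if (is.null(head_offsets)) {
    head_offsets <- list()
    for (dy in c(0, -30, 30)) for (dx in c(0, -50, 50))
      head_offsets[[length(head_offsets) + 1]] <- c(dx, dy, 0)
  }
  seed <- as.integer(seed)
  log_msg <- function(...) if (!quiet) message(sprintf(...))
  # one-point calibration at the central head position
  cal_sim <- simulate_fixation(c(0, 0), geometry, eye, duration_s = 1.2,
                               pixel_noise_sd = pixel_noise_sd, mode = mode,
                               seed = seed)
  raw <- reconstruct_raw(cal_sim$frames_cam1, cal_sim$frames_cam2, geometry)
  calib <- calibrate_one_point(raw, c(0, 0), geometry)
  log_msg("calibration: alpha %.3f deg, beta %.3f deg, K %.4f mm (n = %d)",
          calib$alpha, calib$beta, calib$K, calib$n_samples_used)
  blocks <- vector("list", length(head_offsets))
  for (hp in seq_along(head_offsets)) {
    off <- head_offsets[[hp]]
    windows <- list(); tgt_deg <- NULL
    n_excluded <- 0L
    for (ti in seq_len(nrow(targets))) {
      sim <- simulate_fixation(c(targets$x_mm[ti], targets$y_mm[ti]),
                               geometry, eye, duration_s = duration_s,
                               head_offset_mm = off,
                               pixel_noise_sd = pixel_noise_sd, mode = mode,
                               seed = seed + 1000L * hp + ti)
      gaze <- reconstruct_gaze(sim$frames_cam1, sim$frames_cam2, geometry,
                               calib, filter_width = filter_width)
      use <- gaze$valid
      use[seq_len(min(filter_width, length(use)))] <- FALSE # filter warm-up
      if (sum(use) < 5) { n_excluded <- n_excluded + 1L; next }
      deg <- pog_mm_to_deg(cbind(gaze$pogc_x_mm[use], gaze$pogc_y_mm[use]))
      windows[[length(windows) + 1]] <- data.frame(h = deg[, 1], v = deg[, 2])
      tgt_deg <- rbind(tgt_deg, pog_mm_to_deg(c(targets$x_mm[ti], targets$y_mm[ti])))
    }
    stats <- fixation_metrics(windows, tgt_deg, n_excluded = n_excluded)
    log_msg("head position %d (%+d, %+d mm): MAE %.3f/%.3f deg, %d trials (%d excluded)",
            hp, off[1], off[2], stats$mae_h, stats$mae_v,
            stats$n_trials_used, n_excluded)
    blocks[[hp]] <- list(head_offset_mm = off, metrics = unclass(stats))
  }
  report <- list(seed = seed, mode = mode, pixel_noise_sd = pixel_noise_sd,
                 calibration = unclass(calib), head_positions = blocks)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
  }
  invisible(report)
}
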