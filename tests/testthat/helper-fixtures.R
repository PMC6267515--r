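# Shared fixtures. The reference rig and eye are cheap; the calibrated
# pipeline (noiseless one-point calibration on the reference rig) is
# memoized because several files need it.

test_rig <- function() default_rig()
test_eye <- function() eye_params()

.fixture_env <- new.env(parent = emptyenv())

# noiseless one-point calibration on the reference rig (memoized)
test_calibration <- function() {
  if (is.null(.fixture_env$calib)) {
    geo <- test_rig()
    sim <- simulate_fixation(c(0, 0), geo, test_eye(), duration_s = 0.3, seed = 11)
    raw <- reconstruct_raw(sim$frames_cam1, sim$frames_cam2, geo)
    .fixture_env$calib <- calibrate_one_point(raw, c(0, 0), geo)
  }
  .fixture_env$calib
}

# render a feature-frame stream for an arbitrary orientation trajectory:
# theta_fun/phi_fun give visual-axis angles (deg) as functions of time
render_stream <- function(timestamps, theta_fun, phi_fun, geometry, eye,
                          pixel_noise_sd = 0, seed = NULL) {
  rows <- lapply(timestamps, function(t) {
    e <- orient_eye(eye, theta_fun(t), phi_fun(t), geometry)
    fr <- render_features(e, geometry, pixel_noise_sd = pixel_noise_sd)
    fr$timestamp_s <- t
    fr
  })
  if (!is.null(seed)) {
    # per-stream noise applied afterwards for determinism
  }
  do.call(rbind, rows)
}

# random unit vector
runit3 <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}
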