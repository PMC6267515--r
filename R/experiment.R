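# Synthetic saccade experiment: the validation-study trial structure
# (central fixation, go signal, main-sequence saccade to a peripheral
# target) run through the full simulate -> reconstruct -> detect ->
# main-sequence-fit chain.

#' Run a synthetic saccade experiment and fit the main sequence
#'
#' Simulates one trial per target (steady central fixation, then a
#' raised-cosine saccade whose peak velocity follows the generating main
#' sequence), reconstructs gaze, computes the filtered vectorial velocity,
#' detects the response saccade of each trial (first suprathreshold event
#' after the scripted target onset; median-filter warm-up samples at the
#' trial start are discarded), and fits the saturating main-sequence
#' model to the pooled amplitude / peak-velocity pairs.
#'
#' @param geometry a `system_geometry`.
#' @param eye an `eye_params` at the nominal position.
#' @param calib a `gaze_calibration` for the reconstruction.
#' @param targets target table (screen mm); defaults to the 54-target
#'   grid.
#' @param v0,Amp0 generating main-sequence parameters (deg/s, deg).
#' @param pixel_noise_sd per-frame feature noise, px. The default
#'   reproduces the fixation precision reported for desk trackers of this
#'   class (sample-to-sample RMS a few hundredths of a degree).
#' @param seed integer master seed; trial seeds derive from it.
#' @param target_onset_s,duration_s trial timing, s.
#' @param filter_width median-filter width for the reconstruction.
#' @param velocity_threshold saccade-detection threshold, deg/s.
#' @return list: `pairs` (per-trial `amplitude`, `peak_velocity`,
#'   `true_amplitude`), `fit` (a `main_sequence_fit`), `n_missed` (trials
#'   without a detected response saccade).
#' @export
saccade_experiment <- function(geometry, eye, calib, targets = target_grid(),
                               v0 = 500, Amp0 = 5, pixel_noise_sd = 0.025,
                               seed = 1, target_onset_s = 0.25,
                               duration_s = 0.7, filter_width = 20,
                               velocity_threshold = 45) {
  amps <- numeric(0); vps <- numeric(0); tamps <- numeric(0)
  n_missed <- 0L
  for (i in seq_len(nrow(targets))) {
    sc <- trial_script(c(targets$x_mm[i], targets$y_mm[i]),
                       fixation_xy_mm = c(0, 0),
                       target_onset_s = target_onset_s,
                       duration_s = duration_s, v0 = v0, Amp0 = Amp0,
                       pixel_noise_sd = pixel_noise_sd,
                       seed = as.integer(seed) + 7L * i)
    tr <- simulate_trial(sc, geometry, eye)
    g <- reconstruct_gaze(tr$frames_cam1, tr$frames_cam2, geometry, calib,
                          filter_width = filter_width)
    use <- g$valid
    use[seq_len(min(filter_width, length(use)))] <- FALSE
    if (sum(use) < 50) { n_missed <- n_missed + 1L; next }
    vel <- filter_and_velocity(g$timestamp_s[use], g$theta_corr[use],
                               g$phi_corr[use])
    ev <- detect_saccades(vel, threshold = velocity_threshold)
    ev <- ev[ev$onset_t >= target_onset_s - 0.02, , drop = FALSE]
    if (!nrow(ev)) { n_missed <- n_missed + 1L; next }
    amps <- c(amps, ev$amplitude[1])
    vps <- c(vps, ev$peak_velocity[1])
    a_fix <- fixation_angles(eye, c(0, 0), geometry)
    a_tgt <- fixation_angles(eye, c(targets$x_mm[i], targets$y_mm[i]), geometry)
    tamps <- c(tamps, sqrt(sum((a_tgt - a_fix)^2)))
  }
  fit <- fit_main_sequence(amps, vps)
  list(pairs = data.frame(amplitude = amps, peak_velocity = vps,
                          true_amplitude = tamps),
       fit = fit, n_missed = n_missed)
}
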