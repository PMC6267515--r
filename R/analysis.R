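# Validation analytics: POG unit conversion, zero-phase low-pass
# filtering and vectorial velocity, velocity-threshold saccade detection,
# fixation accuracy/precision metrics, main-sequence fitting and
# Bland-Altman agreement.

#' Convert a screen gaze point from millimeters to degrees
#'
#' Each component is converted independently as `atan(offset / distance)`:
#' the angles describe the orientation of an imaginary eye sitting on the
#' screen axis at the given viewing distance that looks at the same screen
#' point. This per-component decomposition matches the way horizontal and
#' vertical accuracies are reported.
#'
#' @param pog length-2 gaze point (mm) or an n x 2 matrix.
#' @param viewing_distance_mm imaginary-eye distance, mm.
#' @return degrees, same shape as `pog`.
#' @export
pog_mm_to_deg <- function(pog, viewing_distance_mm = 650) {
  if (viewing_distance_mm <= 0)
    sg_stop("viewing distance must be positive", "stereogaze_invalid_input")
  atan(pog / viewing_distance_mm) * 180 / pi
}

#' IIR filtering in transposed direct-form II with an initial state
#' @noRd
iir_filter <- function(b, a, x, zi) {
  n <- length(a) - 1
  z <- zi
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    yi <- b[1] * x[i] + z[1]
    if (n > 1) z[1:(n - 1)] <- b[2:n] * x[i] + z[2:n] - a[2:n] * yi
    z[n] <- b[n + 1] * x[i] - a[n + 1] * yi
    y[i] <- yi
  }
  y
}

#' Forward-backward (zero-phase) filtering with odd-reflection padding and
#' step-matched initial conditions, so that constant signals pass exactly
#' and edges carry no transient
#' @noRd
zero_phase_filter <- function(b, a, x) {
  n <- max(length(a), length(b)) - 1
  # initial state that makes the step response transient-free
  A2 <- cbind(-a[-1], rbind(diag(n - 1), rep(0, n - 1)))
  zi <- solve(diag(n) - A2, b[-1] - b[1] * a[-1])
  npad <- min(3 * (n + 1), length(x) - 1)
  xp <- c(2 * x[1] - x[(npad + 1):2], x,
          2 * x[length(x)] - x[(length(x) - 1):(length(x) - npad)])
  y <- iir_filter(b, a, xp, zi * xp[1])
  y <- rev(iir_filter(b, a, rev(y), zi * y[length(y)]))
  y[(npad + 1):(npad + length(x))]
}

#' Zero-phase low-pass filtering and vectorial eye velocity
#'
#' Resamples the horizontal/vertical gaze-angle traces onto a uniform grid
#' (linear interpolation), applies a zero-phase (forward-backward)
#' Butterworth low-pass filter to each component, differentiates with a
#' central-difference gradient, and combines the component velocities with
#' the Pythagorean sum.
#'
#' @param timestamp_s sample times, s.
#' @param h,v horizontal and vertical gaze angles, deg.
#' @param rate_hz resampling rate (default 500 Hz, i.e. a 2-ms interval).
#' @param order Butterworth order (applied once per direction).
#' @param cutoff_hz low-pass cutoff, Hz.
#' @return data.frame: `timestamp_s` (uniform grid), `h`, `v` (filtered,
#'   deg), `speed` (vectorial velocity, deg/s).
#' @export
filter_and_velocity <- function(timestamp_s, h, v, rate_hz = 500,
                                order = 8, cutoff_hz = 40) {
  dt <- 1 / rate_hz
  t_grid <- seq(min(timestamp_s), max(timestamp_s), by = dt)
  if (length(t_grid) < 3 * order)
    sg_stop("series shorter than the filter warm-up", "stereogaze_invalid_input")
  hu <- stats::approx(timestamp_s, h, xout = t_grid, ties = "ordered")$y
  vu <- stats::approx(timestamp_s, v, xout = t_grid, ties = "ordered")$y
  bf <- signal::butter(order, cutoff_hz / (rate_hz / 2), type = "low")
  hf <- zero_phase_filter(bf$b, bf$a, hu)
  vf <- zero_phase_filter(bf$b, bf$a, vu)
  grad <- function(x) {
    n <- length(x)
    g <- numeric(n)
    g[1] <- (x[2] - x[1]) / dt
    g[n] <- (x[n] - x[n - 1]) / dt
    if (n > 2) g[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
    g
  }
  data.frame(timestamp_s = t_grid, h = hf, v = vf,
             speed = sqrt(grad(hf)^2 + grad(vf)^2))
}

#' Detect saccades with a velocity threshold
#'
#' Saccades are maximal runs of the vectorial velocity above the
#' threshold. Amplitude is the vectorial angular distance between the
#' positions at offset and onset; peak velocity is the maximum within the
#' run. A saccade is flagged corrective when it starts within
#' `corrective_gap_s` of the previous saccade's offset and its amplitude
#' is less than half the previous one's.
#'
#' @param vel output of [filter_and_velocity()] (`timestamp_s`, `h`, `v`,
#'   `speed`).
#' @param threshold velocity threshold, deg/s (default 45).
#' @param corrective_gap_s maximum latency for the corrective-saccade
#'   flag, s.
#' @return data.frame of events: `onset_t`, `offset_t`, `amplitude`,
#'   `peak_velocity`, `is_corrective`; zero rows when nothing crosses the
#'   threshold.
#' @export
detect_saccades <- function(vel, threshold = 45, corrective_gap_s = 0.25) {
  above <- is.finite(vel$speed) & vel$speed > threshold
  empty <- data.frame(onset_t = numeric(0), offset_t = numeric(0),
                      amplitude = numeric(0), peak_velocity = numeric(0),
                      is_corrective = logical(0))
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values)
  ev <- data.frame(
    onset_t = vel$timestamp_s[starts[runs]],
    offset_t = vel$timestamp_s[ends[runs]],
    amplitude = sqrt((vel$h[ends[runs]] - vel$h[starts[runs]])^2 +
                       (vel$v[ends[runs]] - vel$v[starts[runs]])^2),
    peak_velocity = vapply(runs, function(k)
      max(vel$speed[starts[k]:ends[k]]), numeric(1)),
    is_corrective = FALSE
  )
  if (nrow(ev) > 1) {
    for (i in 2:nrow(ev)) {
      ev$is_corrective[i] <- (ev$onset_t[i] - ev$offset_t[i - 1]) <= corrective_gap_s &&
        ev$amplitude[i] < ev$amplitude[i - 1] / 2
    }
  }
  ev
}

#' Fixation analysis window after the targeting saccade
#'
#' The fixation window spans 80 ms and starts 20 ms after the offset of
#' the first saccade of the trial, or 20 ms after its corrective
#' follower's offset when one occurred.
#'
#' @param events saccade events from [detect_saccades()] for one trial.
#' @param window_s window length, s.
#' @param delay_s gap between saccade offset and window start, s.
#' @return c(start, end), s.
#' @section Errors: `stereogaze_no_saccade` when the trial contains no
#'   saccade (the trial is then excluded and counted by the caller).
#' @export
fixation_window <- function(events, window_s = 0.080, delay_s = 0.020) {
  if (!nrow(events))
    sg_stop("no saccade detected in trial; excluded from fixation analysis",
            "stereogaze_no_saccade")
  anchor <- events$offset_t[1]
  if (nrow(events) >= 2 && events$is_corrective[2])
    anchor <- events$offset_t[2]
  c(anchor + delay_s, anchor + delay_s + window_s)
}

#' Fixation accuracy and precision metrics
#'
#' Accuracy is the mean absolute error between the per-trial mean gaze
#' position in the fixation window and the target, horizontal and
#' vertical separately. Precision is reported two ways, each computed per
#' window and averaged over trials: the root-mean-square of successive
#' sample displacements (RMS-s2s, intersample noise) and the standard
#' deviation of the samples (dispersion).
#'
#' @param windows list of per-trial data.frames with columns `h`, `v`
#'   (gaze angles in the fixation window, deg); trials with any
#'   non-finite sample must already be excluded.
#' @param targets matrix or data.frame of per-trial target angles (deg),
#'   columns horizontal and vertical, one row per element of `windows`.
#' @param n_excluded count of excluded trials, carried into the result.
#' @return list of class `fixation_stats`: `mae_h`, `mae_v`, `rms_s2s_h`,
#'   `rms_s2s_v`, `sd_h`, `sd_v` (deg), `n_trials_used`,
#'   `n_trials_excluded`.
#' @export
fixation_metrics <- function(windows, targets, n_excluded = 0) {
  if (!length(windows))
    sg_stop("no included trials for the fixation analysis",
            "stereogaze_invalid_input")
  targets <- as.matrix(targets)
  err_h <- numeric(length(windows)); err_v <- numeric(length(windows))
  rms_h <- numeric(length(windows)); rms_v <- numeric(length(windows))
  sd_h <- numeric(length(windows)); sd_v <- numeric(length(windows))
  for (i in seq_along(windows)) {
    w <- windows[[i]]
    err_h[i] <- abs(mean(w$h) - targets[i, 1])
    err_v[i] <- abs(mean(w$v) - targets[i, 2])
    rms_h[i] <- sqrt(mean(diff(w$h)^2))
    rms_v[i] <- sqrt(mean(diff(w$v)^2))
    sd_h[i] <- stats::sd(w$h)
    sd_v[i] <- stats::sd(w$v)
  }
  structure(list(mae_h = mean(err_h), mae_v = mean(err_v),
                 rms_s2s_h = mean(rms_h), rms_s2s_v = mean(rms_v),
                 sd_h = mean(sd_h), sd_v = mean(sd_v),
                 n_trials_used = length(windows),
                 n_trials_excluded = n_excluded),
            class = "fixation_stats")
}

#' @export
print.fixation_stats <- function(x, ...) {
  cat(sprintf("<fixation_stats> MAE (h/v) %.3f / %.3f deg, RMS-s2s %.4f / %.4f deg, SD %.4f / %.4f deg (%d trials, %d excluded)\n",
              x$mae_h, x$mae_v, x$rms_s2s_h, x$rms_s2s_v, x$sd_h, x$sd_v,
              x$n_trials_used, x$n_trials_excluded))
  invisible(x)
}

#' Fit the saccadic main sequence
#'
#' Nonlinear least squares of the saturating-exponential main-sequence
#' model `v_peak = v0 * (1 - exp(-Amp / Amp0))` over amplitude /
#' peak-velocity pairs.
#'
#' @param amplitude saccade amplitudes, deg.
#' @param peak_velocity peak velocities, deg/s.
#' @return list of class `main_sequence_fit`: `v0` (deg/s), `Amp0` (deg),
#'   `rmse` (deg/s).
#' @export
fit_main_sequence <- function(amplitude, peak_velocity) {
  ok <- is.finite(amplitude) & is.finite(peak_velocity)
  amplitude <- amplitude[ok]; peak_velocity <- peak_velocity[ok]
  if (length(unique(round(amplitude, 6))) < 3)
    sg_stop("main-sequence fit needs >= 3 distinct amplitudes",
            "stereogaze_fit_error")
  df <- data.frame(A = amplitude, vp = peak_velocity)
  fit <- tryCatch(
    minpack.lm::nlsLM(vp ~ v0 * (1 - exp(-A / A0)), data = df,
                      start = list(v0 = max(peak_velocity) * 1.05,
                                   A0 = max(stats::median(amplitude) / 2, 0.5)),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) sg_stop(paste("main-sequence fit failed:",
                                      conditionMessage(e)),
                                "stereogaze_fit_error"))
  cf <- stats::coef(fit)
  structure(list(v0 = unname(cf["v0"]), Amp0 = unname(cf["A0"]),
                 rmse = sqrt(mean(stats::resid(fit)^2))),
            class = "main_sequence_fit")
}

#' @export
print.main_sequence_fit <- function(x, ...) {
  cat(sprintf("<main_sequence_fit> v0 = %.1f deg/s, Amp0 = %.2f deg, RMSE = %.2f deg/s\n",
              x$v0, x$Amp0, x$rmse))
  invisible(x)
}

#' Bland-Altman agreement between paired measurements
#'
#' Mean difference and 95% limits of agreement (mean +/- 1.96 SD of the
#' paired differences).
#'
#' @param a,b equal-length paired measurement vectors.
#' @return list: `mean_diff`, `ci_low`, `ci_high`, `sd_diff`.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b))
    sg_stop("Bland-Altman inputs must be the same length", "stereogaze_invalid_input")
  d <- a - b
  s <- stats::sd(d)
  if (length(d) == 1 || !is.finite(s)) s <- 0
  list(mean_diff = mean(d), ci_low = mean(d) - 1.96 * s,
       ci_high = mean(d) + 1.96 * s, sd_diff = s)
}

#' Expected SD of between-system amplitude differences
#'
#' Error-propagation check for the agreement analysis: if two tracking
#' systems have independent horizontal/vertical fixation accuracies, the
#' expected standard deviation of their trial-to-trial amplitude
#' difference is the root sum of squares of the four accuracies; the
#' conventional 95% interval half-width companion is twice this value.
#'
#' @param acc_h_a,acc_v_a horizontal/vertical accuracy of system A, deg.
#' @param acc_h_b,acc_v_b horizontal/vertical accuracy of system B, deg.
#' @return expected SD, deg; attribute `ci_half_width` = 2 x SD.
#' @export
expected_amplitude_diff_sd <- function(acc_h_a, acc_v_a, acc_h_b, acc_v_b) {
  if (any(c(acc_h_a, acc_v_a, acc_h_b, acc_v_b) < 0))
    sg_stop("accuracies must be non-negative", "stereogaze_invalid_input")
  s <- sqrt(acc_h_a^2 + acc_v_a^2 + acc_h_b^2 + acc_v_b^2)
  attr(s, "ci_half_width") <- 2 * s
  s
}
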