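# Offline stereo gaze reconstruction. Per synchronized frame pair:
#   1. triangulate the virtual pupil from the two pupil images;
#   2. triangulate each illuminator's virtual image from its two glints,
#      then intersect the two illuminator->virtual-image axes to get the
#      center of corneal curvature c (convex-mirror geometry: every
#      reflected ray of an illuminator's pencil, extended backward,
#      crosses the illuminator-to-sphere-center axis);
#   3. re-impose the calibrated corneal-center-to-pupil distance K on the
#      virtual pupil's depth (image noise mainly corrupts the tracker
#      z-axis, so x/y are kept and z is solved from K);
#   4. map c and the constrained pupil into the stimulus frame, median
#      filter, convert to pan/tilt angles, add the calibrated visual-axis
#      offsets, intersect with the screen plane (Z = 0);
#   5. rescale the point of gaze by K / K_actual, where K_actual is the
#      median-filtered measured |c - p_v|, to attenuate the systematic
#      gaze-angle errors that arise when the measured vector length
#      deviates from K.

#' Synchronize two asynchronously sampled feature streams
#'
#' The two cameras free-run at independent rates, so each camera's pixel
#' features are linearly interpolated at the other camera's timestamps.
#' The output contains one paired record per input timestamp of either
#' camera inside the temporal overlap. A record is invalid when the raw
#' frame was invalid, when an interpolation bracket is invalid, or when
#' interpolation would bridge more than two dropped frames.
#'
#' @param frames_cam1,frames_cam2 data.frames with columns `timestamp_s`,
#'   `pupil_x`, `pupil_y`, `glint1_x`, `glint1_y`, `glint2_x`, `glint2_y`,
#'   `valid`, time-sorted.
#' @param max_bridge maximum number of consecutive invalid frames an
#'   interpolation interval may span.
#' @return data.frame with `timestamp_s`, `source_cam`, the six feature
#'   columns suffixed `_1` and `_2` for the two cameras, and `valid`.
#' @export
synchronize_frames <- function(frames_cam1, frames_cam2, max_bridge = 2) {
  t_lo <- max(min(frames_cam1$timestamp_s), min(frames_cam2$timestamp_s))
  t_hi <- min(max(frames_cam1$timestamp_s), max(frames_cam2$timestamp_s))
  if (t_lo > t_hi) {
    warning("feature streams do not overlap in time; empty synchronization")
    return(data.frame())
  }
  cols <- c("pupil_x", "pupil_y", "glint1_x", "glint1_y", "glint2_x", "glint2_y")
  interp_at <- function(frames, t_out) {
    vi <- which(frames$valid)
    out <- matrix(NA_real_, length(t_out), length(cols),
                  dimnames = list(NULL, cols))
    ok <- rep(FALSE, length(t_out))
    if (length(vi) >= 1) {
      tv <- frames$timestamp_s[vi]
      exact <- match(t_out, tv)
      j <- findInterval(t_out, tv)
      inb <- !is.na(exact) | (j >= 1 & j < length(vi))
      # disallow bridging long invalid gaps (raw-frame index distance)
      gap_ok <- rep(FALSE, length(t_out))
      gap_ok[!is.na(exact)] <- TRUE
      mid <- is.na(exact) & j >= 1 & j < length(vi)
      gap_ok[mid] <- (vi[pmin(j[mid] + 1, length(vi))] - vi[pmax(j[mid], 1)]) <= max_bridge + 1
      ok <- inb & gap_ok
      if (any(ok) && length(vi) >= 2) {
        for (cc in cols)
          out[ok, cc] <- stats::approx(tv, frames[[cc]][vi], xout = t_out[ok],
                                       ties = "ordered")$y
      } else if (any(ok)) { # single valid frame: exact matches only
        for (cc in cols) out[ok, cc] <- frames[[cc]][vi][exact[ok]]
      }
    }
    list(values = out, valid = ok)
  }
  t1 <- frames_cam1$timestamp_s; t2 <- frames_cam2$timestamp_s
  sel1 <- t1 >= t_lo & t1 <= t_hi
  sel2 <- t2 >= t_lo & t2 <= t_hi
  t_out <- c(t1[sel1], t2[sel2])
  src <- c(rep(1L, sum(sel1)), rep(2L, sum(sel2)))
  a1 <- interp_at(frames_cam1, t_out)
  a2 <- interp_at(frames_cam2, t_out)
  # a camera's own timestamps keep the raw (possibly invalid) frame values
  own1 <- which(src == 1L); own2 <- which(src == 2L)
  a1$values[own1, ] <- as.matrix(frames_cam1[sel1, cols])
  a1$valid[own1] <- frames_cam1$valid[sel1]
  a2$values[own2, ] <- as.matrix(frames_cam2[sel2, cols])
  a2$valid[own2] <- frames_cam2$valid[sel2]
  v1 <- a1$values; colnames(v1) <- paste0(cols, "_1")
  v2 <- a2$values; colnames(v2) <- paste0(cols, "_2")
  out <- data.frame(timestamp_s = t_out, source_cam = src, v1, v2,
                    valid = a1$valid & a2$valid)
  out <- out[order(out$timestamp_s), ]
  rownames(out) <- NULL
  out
}

#' Triangulate the virtual pupil center for one frame pair
#'
#' @param pair one row of the output of [synchronize_frames()].
#' @param geometry a `system_geometry`.
#' @return length-3 point, mm, tracker frame.
#' @export
estimate_virtual_pupil <- function(pair, geometry) {
  triangulate_rays(
    back_project(geometry$camera1, c(pair$pupil_x_1, pair$pupil_y_1)),
    back_project(geometry$camera2, c(pair$pupil_x_2, pair$pupil_y_2))
  )$point
}

#' Estimate the center of corneal curvature for one frame pair
#'
#' For each illuminator the virtual image behind the cornea is
#' triangulated from the two glint back-projections; the two lines from
#' each illuminator through its virtual image are then intersected.
#'
#' @inheritParams estimate_virtual_pupil
#' @return list with `c` (length-3 corneal-curvature center, mm) and
#'   `residual_mm` (the final two-line residual).
#' @export
estimate_corneal_center <- function(pair, geometry) {
  L1v <- triangulate_rays(
    back_project(geometry$camera1, c(pair$glint1_x_1, pair$glint1_y_1)),
    back_project(geometry$camera2, c(pair$glint1_x_2, pair$glint1_y_2))
  )$point
  L2v <- triangulate_rays(
    back_project(geometry$camera1, c(pair$glint2_x_1, pair$glint2_y_1)),
    back_project(geometry$camera2, c(pair$glint2_x_2, pair$glint2_y_2))
  )$point
  tri <- triangulate_rays(ray3(geometry$illuminator1, L1v - geometry$illuminator1),
                          ray3(geometry$illuminator2, L2v - geometry$illuminator2))
  list(c = tri$point, residual_mm = tri$residual_mm)
}

#' Impose the calibrated K on the virtual pupil depth
#'
#' Keeps the x/y coordinates of the virtual pupil and solves its
#' z-coordinate so that the distance to the corneal-curvature center
#' equals K. The negative root is taken: in tracker coordinates the pupil
#' lies nearer the cameras than the corneal center.
#'
#' @param c_est corneal-curvature center, mm.
#' @param p_v virtual pupil center, mm.
#' @param K calibrated corneal-center-to-pupil distance, mm.
#' @return the constrained pupil center (length-3, mm).
#' @section Errors: `stereogaze_invalid_sample` when the planar distance
#'   already exceeds K (no real root).
#' @export
apply_k_constraint <- function(c_est, p_v, K) {
  d2 <- K^2 - (c_est[1] - p_v[1])^2 - (c_est[2] - p_v[2])^2
  if (d2 < 0)
    sg_stop("planar pupil-to-c distance exceeds K; sample flagged invalid",
            "stereogaze_invalid_sample")
  c(p_v[1], p_v[2], c_est[3] - sqrt(d2))
}

#' Pan/tilt angles of the optical axis
#'
#' Fick-style decomposition of the unit vector from the corneal center to
#' the (constrained) virtual pupil, both in the stimulus frame: pan theta
#' from the horizontal component, tilt phi from the vertical one; (0, 0)
#' is a gaze along -Z, straight into the screen.
#'
#' @param C corneal-curvature center, stimulus frame, mm.
#' @param P_v_prime constrained virtual pupil, stimulus frame, mm.
#' @return c(theta, phi), degrees.
#' @export
optical_axis_angles <- function(C, P_v_prime) {
  d <- as.numeric(P_v_prime) - as.numeric(C)
  n <- sqrt(sum(d^2))
  if (n < 1e-12)
    sg_stop("coincident corneal center and pupil; axis undefined",
            "stereogaze_invalid_sample")
  vec_to_angles(d / n)
}

#' Reconstruct tracker-frame eye geometry per frame pair
#'
#' The calibration-independent first half of the pipeline: synchronize
#' the two camera streams, then triangulate the virtual pupil and the
#' corneal-curvature center for every valid pair. `K_raw` is the measured
#' `|c - p_v|` per pair, before any filtering.
#'
#' @inheritParams synchronize_frames
#' @param geometry a `system_geometry`.
#' @return data.frame: `timestamp_s`, `cx, cy, cz`, `pvx, pvy, pvz`,
#'   `K_raw`, `valid`.
#' @export
reconstruct_raw <- function(frames_cam1, frames_cam2, geometry) {
  pairs <- synchronize_frames(frames_cam1, frames_cam2)
  n <- nrow(pairs)
  out <- data.frame(timestamp_s = pairs$timestamp_s,
                    cx = NA_real_, cy = NA_real_, cz = NA_real_,
                    pvx = NA_real_, pvy = NA_real_, pvz = NA_real_,
                    K_raw = NA_real_, valid = FALSE)
  if (!n) return(out)
  for (i in which(pairs$valid)) {
    row <- pairs[i, ]
    res <- tryCatch({
      pv <- estimate_virtual_pupil(row, geometry)
      cc <- estimate_corneal_center(row, geometry)
      list(pv = pv, c = cc$c)
    }, stereogaze_error = function(e) NULL)
    if (is.null(res)) next
    out[i, c("cx", "cy", "cz")] <- res$c
    out[i, c("pvx", "pvy", "pvz")] <- res$pv
    out$K_raw[i] <- sqrt(sum((res$c - res$pv)^2))
    out$valid[i] <- TRUE
  }
  out
}

#' One-point calibration
#'
#' From a window of steady fixation of a known target: K is the median of
#' the measured `|c - p_v|`; the visual-axis offsets alpha and beta are
#' the medians of the per-sample differences between the line-of-sight
#' angles (from the corneal center to the target, same pan/tilt
#' parameterization as the optical axis, which makes the offsets exactly
#' additive) and the optical-axis angles.
#'
#' @param raw output of [reconstruct_raw()] during the calibration
#'   fixation.
#' @param target_xy_mm calibration-target position, stimulus frame, mm
#'   (length 2; a length-3 screen point with Z = 0 is accepted).
#' @param geometry a `system_geometry`.
#' @param min_samples minimum number of valid samples required.
#' @param filter_width median-filter width applied to the stimulus-frame
#'   corneal-center and pupil components before angle extraction, matching
#'   the runtime reconstruction pipeline; K is always the median of the
#'   raw per-sample lengths.
#' @return object of class `gaze_calibration`: `alpha`, `beta` (deg), `K`
#'   (mm), `n_samples_used`.
#' @export
calibrate_one_point <- function(raw, target_xy_mm, geometry, min_samples = 20,
                                filter_width = 20) {
  ok <- which(raw$valid)
  if (length(ok) < min_samples)
    sg_stop(sprintf("one-point calibration needs >= %d valid samples, got %d",
                    min_samples, length(ok)), "stereogaze_calibration_error")
  target <- c(as.numeric(target_xy_mm)[1:2], 0)
  K <- stats::median(raw$K_raw[ok])
  n <- nrow(raw)
  pk <- matrix(NA_real_, n, 3)
  for (i in ok) {
    res <- tryCatch(apply_k_constraint(c(raw$cx[i], raw$cy[i], raw$cz[i]),
                                       c(raw$pvx[i], raw$pvy[i], raw$pvz[i]), K),
                    stereogaze_error = function(e) NULL)
    if (!is.null(res)) pk[i, ] <- res
  }
  ctr <- cbind(raw$cx, raw$cy, raw$cz)
  ctr[!raw$valid, ] <- NA_real_
  Cs <- to_screen_frame(ctr, geometry)
  Ps <- to_screen_frame(pk, geometry)
  if (filter_width > 1) {
    for (j in 1:3) {
      Cs[, j] <- median_filter_track(Cs[, j], filter_width)
      Ps[, j] <- median_filter_track(Ps[, j], filter_width)
    }
  }
  use <- which(stats::complete.cases(Cs) & stats::complete.cases(Ps))
  dth <- rep(NA_real_, length(use)); dph <- rep(NA_real_, length(use))
  for (j in seq_along(use)) {
    i <- use[j]
    opt <- tryCatch(optical_axis_angles(Cs[i, ], Ps[i, ]),
                    stereogaze_error = function(e) NULL)
    if (is.null(opt)) next
    sight <- vec_to_angles(unitize(target - Cs[i, ]))
    dth[j] <- sight[1] - opt[1]
    dph[j] <- sight[2] - opt[2]
  }
  alpha <- stats::median(dth, na.rm = TRUE)
  beta <- stats::median(dph, na.rm = TRUE)
  if (!is.finite(alpha) || !is.finite(beta) || abs(alpha) > 15 || abs(beta) > 15 || K <= 0)
    sg_stop("one-point calibration outside sanity bounds", "stereogaze_calibration_error")
  structure(list(alpha = alpha, beta = beta, K = K,
                 n_samples_used = sum(is.finite(dth))),
            class = "gaze_calibration")
}

#' @export
print.gaze_calibration <- function(x, ...) {
  cat(sprintf("<gaze_calibration> alpha = %.3f deg, beta = %.3f deg, K = %.4f mm (n = %d)\n",
              x$alpha, x$beta, x$K, x$n_samples_used))
  invisible(x)
}

#' Intersect the visual axis with the screen plane
#'
#' Builds the unit gaze vector from the optical-axis angles plus the
#' calibrated offsets and intersects the line through the corneal center
#' with the screen plane Z = 0.
#'
#' @param C corneal-curvature center, stimulus frame, mm (Z > 0).
#' @param theta,phi optical-axis angles, deg.
#' @param calib a `gaze_calibration`.
#' @return list with `pog` (length-2 screen mm), `lambda_g` (mm) and
#'   `gaze` (unit gaze vector).
#' @export
point_of_gaze <- function(C, theta, phi, calib) {
  th <- (theta + calib$alpha) * pi / 180
  ph <- (phi + calib$beta) * pi / 180
  denom <- cos(ph) * cos(th)
  if (denom <= 1e-12 || C[3] <= 0)
    sg_stop("gaze does not intersect the screen in front of the eye",
            "stereogaze_invalid_sample")
  g <- c(cos(ph) * sin(th), sin(ph), -cos(ph) * cos(th))
  lambda_g <- C[3] / denom
  pog3 <- as.numeric(C) + lambda_g * g
  list(pog = pog3[1:2], lambda_g = lambda_g, gaze = g)
}

#' K-gain correction of the point of gaze
#'
#' Rescales the full gaze point vector (eye-position term plus gaze
#' direction term) by `K / K_actual`, where `K_actual` is the filtered
#' measured `|c - p_v|`; corrected gaze angles are recomputed from the
#' corrected point of gaze and the (unscaled) corneal center. When the
#' measured length equals K the correction is the identity.
#'
#' @param C corneal center, stimulus frame, mm.
#' @param pog uncorrected gaze point, length-2 screen mm.
#' @param K calibrated distance, mm.
#' @param K_actual_filtered filtered measured distance, mm.
#' @return list with `pog_corrected` (length-2 mm), `theta_corr`,
#'   `phi_corr` (deg).
#' @export
correct_pog <- function(C, pog, K, K_actual_filtered) {
  if (!is.finite(K_actual_filtered) || K_actual_filtered <= 0)
    sg_stop("K_actual must be positive", "stereogaze_invalid_sample")
  gain <- K / K_actual_filtered
  pogc3 <- gain * c(pog[1], pog[2], 0)
  gc <- unitize(pogc3 - as.numeric(C))
  a <- vec_to_angles(gc)
  list(pog_corrected = pogc3[1:2],
       theta_corr = unname(a[1]), phi_corr = unname(a[2]))
}

#' Sliding-window median filter
#'
#' Length-preserving windowed median with the window centered as closely
#' as parity allows (for even widths the window extends `width/2` samples
#' back and `width/2 - 1` forward); edge windows are truncated to the
#' available samples, and even-cardinality windows use the mean of the two
#' middle order statistics. Missing values are ignored within a window;
#' positions that are themselves NA stay NA.
#'
#' @param x numeric series.
#' @param width window width in samples (default 20).
#' @return filtered series, same length as `x`.
#' @export
median_filter_track <- function(x, width = 20) {
  if (width < 1) sg_stop("filter width must be >= 1", "stereogaze_invalid_input")
  n <- length(x)
  if (!n) return(x)
  back <- floor(width / 2)
  fwd <- ceiling(width / 2) - 1
  out <- x
  for (i in seq_len(n)) {
    if (is.na(x[i])) next
    w <- x[max(1, i - back):min(n, i + fwd)]
    out[i] <- stats::median(w, na.rm = TRUE)
  }
  out
}

#' Full offline gaze reconstruction
#'
#' Runs the complete pipeline on two feature streams: synchronization,
#' per-pair triangulation of the virtual pupil and corneal center, the K
#' depth constraint, mapping into the stimulus frame, component-wise
#' median filtering of the corneal center, the constrained pupil and the
#' measured K, angle extraction, screen intersection, and the K-gain
#' correction. Invalid frames propagate as invalid samples (never
#' interpolated through at this stage).
#'
#' @inheritParams synchronize_frames
#' @param geometry a `system_geometry`.
#' @param calib a `gaze_calibration`.
#' @param filter_width median-filter width in samples; 1 disables
#'   smoothing.
#' @param correction apply the K-gain correction (on by default).
#' @param k_constraint impose the calibrated K on the virtual-pupil depth
#'   (on by default); disabling it, together with `filter_width = 1`,
#'   gives the raw noise-uncompensated pipeline for paired comparisons.
#' @param eye_label label copied into the `eye` column.
#' @return data.frame (one row per synchronized timestamp):
#'   `timestamp_s`, `eye`, `Cx, Cy, Cz`, `theta`, `phi`, `theta_corr`,
#'   `phi_corr`, `pog_x_mm`, `pog_y_mm`, `pogc_x_mm`, `pogc_y_mm`,
#'   `K_actual`, `valid`.
#' @export
reconstruct_gaze <- function(frames_cam1, frames_cam2, geometry, calib,
                             filter_width = 20, correction = TRUE,
                             k_constraint = TRUE, eye_label = "right") {
  raw <- reconstruct_raw(frames_cam1, frames_cam2, geometry)
  n <- nrow(raw)
  out <- data.frame(timestamp_s = raw$timestamp_s, eye = rep(eye_label, n),
                    Cx = NA_real_, Cy = NA_real_, Cz = NA_real_,
                    theta = NA_real_, phi = NA_real_,
                    theta_corr = NA_real_, phi_corr = NA_real_,
                    pog_x_mm = NA_real_, pog_y_mm = NA_real_,
                    pogc_x_mm = NA_real_, pogc_y_mm = NA_real_,
                    K_actual = NA_real_, valid = FALSE)
  if (!n) return(out)
  # K depth constraint in tracker frame
  pk <- matrix(NA_real_, n, 3)
  valid <- raw$valid
  if (k_constraint) {
    for (i in which(valid)) {
      res <- tryCatch(apply_k_constraint(c(raw$cx[i], raw$cy[i], raw$cz[i]),
                                         c(raw$pvx[i], raw$pvy[i], raw$pvz[i]),
                                         calib$K),
                      stereogaze_error = function(e) NULL)
      if (is.null(res)) valid[i] <- FALSE else pk[i, ] <- res
    }
  } else {
    pk[valid, ] <- cbind(raw$pvx, raw$pvy, raw$pvz)[valid, , drop = FALSE]
  }
  ctr <- cbind(raw$cx, raw$cy, raw$cz)
  Cs <- to_screen_frame(ifelse(valid, 1, NA_real_) * ctr, geometry)
  Ps <- to_screen_frame(pk, geometry)
  K_actual <- ifelse(valid, raw$K_raw, NA_real_)
  if (filter_width > 1) {
    for (j in 1:3) {
      Cs[, j] <- median_filter_track(Cs[, j], filter_width)
      Ps[, j] <- median_filter_track(Ps[, j], filter_width)
    }
    K_actual <- median_filter_track(K_actual, filter_width)
  }
  d <- Ps - Cs
  nd <- sqrt(rowSums(d^2))
  theta <- atan2(d[, 1], -d[, 3]) * 180 / pi
  phi <- asin(pmin(1, pmax(-1, d[, 2] / nd))) * 180 / pi
  th <- (theta + calib$alpha) * pi / 180
  ph <- (phi + calib$beta) * pi / 180
  denom <- cos(ph) * cos(th)
  valid <- valid & is.finite(denom) & denom > 1e-12 & Cs[, 3] > 0 & nd > 1e-12
  lambda_g <- Cs[, 3] / denom
  pog_x <- Cs[, 1] + lambda_g * cos(ph) * sin(th)
  pog_y <- Cs[, 2] + lambda_g * sin(ph)
  out$Cx <- Cs[, 1]; out$Cy <- Cs[, 2]; out$Cz <- Cs[, 3]
  out$theta <- theta; out$phi <- phi
  out$pog_x_mm <- pog_x; out$pog_y_mm <- pog_y
  out$K_actual <- K_actual
  if (correction) {
    gain <- calib$K / K_actual
    pcx <- gain * pog_x; pcy <- gain * pog_y
    gx <- pcx - Cs[, 1]; gy <- pcy - Cs[, 2]; gz <- -Cs[, 3]
    gn <- sqrt(gx^2 + gy^2 + gz^2)
    out$pogc_x_mm <- pcx; out$pogc_y_mm <- pcy
    out$theta_corr <- atan2(gx, -gz) * 180 / pi
    out$phi_corr <- asin(pmin(1, pmax(-1, gy / gn))) * 180 / pi
    valid <- valid & is.finite(gain) & gain > 0
  } else {
    out$pogc_x_mm <- pog_x; out$pogc_y_mm <- pog_y
    out$theta_corr <- theta + calib$alpha
    out$phi_corr <- phi + calib$beta
  }
  out$valid <- valid & stats::complete.cases(out[, c("pog_x_mm", "pog_y_mm",
                                                    "pogc_x_mm", "pogc_y_mm")])
  out
}
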