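# Forward ray-tracing model of the eye and rig. The cornea is a spherical
# surface of radius `corneal_radius` centered on `corneal_center`; glints
# form by specular reflection off that sphere (convex mirror), and the
# pupil is imaged either directly (no-refraction mode, which makes the
# inverse problem exact and is the basis of all round-trip tests) or
# through Snell refraction at the anterior surface. The optical axis
# passes through the corneal center and the pupil center; the visual axis
# is offset from it by the angles alpha (horizontal) and beta (vertical).

#' Run an expression with a temporary RNG seed
#' @noRd
with_seed_sg <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Construct simulated eye parameters
#'
#' Defaults follow standard schematic-eye values: a 7.8-mm anterior
#' corneal radius, a 4.2-mm corneal-center-to-pupil distance K, visual
#' axis offset 5 deg horizontally and 1.5 deg vertically from the optical
#' axis, and an aqueous/corneal refractive index of 1.3375.
#'
#' @param corneal_center center of corneal curvature, tracker frame, mm.
#' @param corneal_radius anterior corneal radius, mm.
#' @param K_true corneal-center-to-pupil-center distance, mm.
#' @param alpha_true,beta_true horizontal/vertical visual-axis offsets, deg.
#' @param pupil_radius pupil radius, mm (used by the raster renderer only).
#' @param refractive_index index inside the cornea for Snell-mode imaging.
#' @param optical_axis unit vector along the optical axis, pointing away
#'   from the eye toward the stimulus.
#' @return object of class `eye_params`.
#' @export
eye_params <- function(corneal_center = c(60, 180, 600),
                       corneal_radius = 7.8, K_true = 4.2,
                       alpha_true = 5.0, beta_true = 1.5,
                       pupil_radius = 2.0, refractive_index = 1.3375,
                       optical_axis = c(0, 0, -1)) {
  if (corneal_radius <= 0 || K_true <= 0)
    sg_stop("corneal_radius and K_true must be positive", "stereogaze_invalid_input")
  structure(list(
    corneal_center = as.numeric(corneal_center),
    corneal_radius = corneal_radius, K_true = K_true,
    alpha_true = alpha_true, beta_true = beta_true,
    pupil_radius = pupil_radius, refractive_index = refractive_index,
    optical_axis = unitize(as.numeric(optical_axis))
  ), class = "eye_params")
}

#' @export
print.eye_params <- function(x, ...) {
  cat(sprintf("<eye_params> c = (%.1f, %.1f, %.1f) mm, R = %.2f mm, K = %.2f mm, alpha = %.1f deg, beta = %.1f deg, n = %.4f\n",
              x$corneal_center[1], x$corneal_center[2], x$corneal_center[3],
              x$corneal_radius, x$K_true, x$alpha_true, x$beta_true,
              x$refractive_index))
  invisible(x)
}

#' True pupil center of a simulated eye
#'
#' The pupil center lies on the optical axis at distance `K_true` from the
#' corneal-curvature center, on the stimulus side.
#'
#' @param eye an `eye_params`.
#' @return length-3 point, mm, tracker frame.
#' @export
pupil_center <- function(eye) eye$corneal_center + eye$K_true * eye$optical_axis

#' Unit gaze vector from pan/tilt angles (degrees)
#'
#' The Fick-style parameterization used throughout: horizontal pan theta,
#' vertical tilt phi, with (0, 0) mapping to (0, 0, -1), i.e. looking
#' straight at the screen along -Z of the stimulus frame.
#' @noRd
angles_to_vec <- function(theta_deg, phi_deg) {
  th <- theta_deg * pi / 180; ph <- phi_deg * pi / 180
  c(cos(ph) * sin(th), sin(ph), -cos(ph) * cos(th))
}

#' Pan/tilt angles (degrees) of a unit gaze vector
#' @noRd
vec_to_angles <- function(v) {
  c(theta = atan2(v[1], -v[3]) * 180 / pi,
    phi = asin(pmin(1, pmax(-1, v[2]))) * 180 / pi)
}

#' Orient a simulated eye from visual-axis angles
#'
#' Sets the optical axis so that the eye's visual axis points along the
#' given stimulus-frame pan/tilt angles; the optical axis is offset from
#' the visual axis by `-alpha_true` / `-beta_true` in the additive angle
#' parameterization the reconstruction assumes.
#'
#' @param eye an `eye_params`.
#' @param theta_vis_deg,phi_vis_deg visual-axis angles, stimulus frame, deg.
#' @param geometry a `system_geometry` (for the screen rotation).
#' @return the eye with an updated `optical_axis`.
#' @export
orient_eye <- function(eye, theta_vis_deg, phi_vis_deg, geometry) {
  w_screen <- angles_to_vec(theta_vis_deg - eye$alpha_true,
                            phi_vis_deg - eye$beta_true)
  eye$optical_axis <- as.numeric(t(geometry$screen_rotation) %*% w_screen)
  eye
}

#' Visual-axis angles that fixate a screen target
#'
#' @param eye an `eye_params` (its corneal center is the vantage point).
#' @param target_xy_mm length-2 target position on the screen, mm.
#' @param geometry a `system_geometry`.
#' @return c(theta, phi) in degrees, stimulus frame.
#' @export
fixation_angles <- function(eye, target_xy_mm, geometry) {
  C <- to_screen_frame(eye$corneal_center, geometry)
  d <- unitize(c(target_xy_mm[1], target_xy_mm[2], 0) - C)
  vec_to_angles(d)
}

#' Point a simulated eye at a screen target
#'
#' @inheritParams fixation_angles
#' @return the eye with its optical axis set so the visual axis passes
#'   through the target.
#' @export
fixate_target <- function(eye, target_xy_mm, geometry) {
  a <- fixation_angles(eye, target_xy_mm, geometry)
  orient_eye(eye, a[1], a[2], geometry)
}

#' Glint (corneal reflection) pixel position
#'
#' Finds the specular point on the corneal sphere for the illuminator ->
#' surface -> camera-nodal-point path. By symmetry the specular point lies
#' in the plane spanned by the illuminator, the nodal point and the sphere
#' center, so Fermat's principle reduces to a 1-D root-find on the
#' in-plane surface angle: the optical path length is stationary where the
#' reflection law holds. The surface point is then projected into the
#' camera.
#'
#' @param eye an `eye_params`.
#' @param camera a `camera_model`.
#' @param illuminator length-3 illuminator position, mm.
#' @return length-2 pixel vector; attribute `surface_point` carries the
#'   3-D specular point (mm) for diagnostic checks of the reflection law.
#' @section Errors: `stereogaze_no_glint` when no specular path exists on
#'   the camera-facing hemisphere.
#' @export
glint_pixel <- function(eye, camera, illuminator) {
  c0 <- eye$corneal_center; R <- eye$corneal_radius
  Lr <- as.numeric(illuminator) - c0
  Or <- camera$nodal_point - c0
  if (sqrt(sum(Lr^2)) <= R || sqrt(sum(Or^2)) <= R)
    sg_stop("illuminator or camera inside the corneal sphere", "stereogaze_no_glint")
  e1 <- unitize(Lr)
  perp <- Or - sum(Or * e1) * e1
  if (sqrt(sum(perp^2)) < 1e-12 * sqrt(sum(Or^2))) {
    # collinear: retro-reflective only if camera and illuminator on the same side
    if (sum(Or * e1) <= 0)
      sg_stop("no specular path: camera opposite the illuminator", "stereogaze_no_glint")
    s <- c0 + R * unitize(Or)
    px <- project_point(camera, s)
    attr(px, "surface_point") <- s
    return(px)
  }
  e2 <- unitize(perp)
  ang <- atan2(sum(Or * e2), sum(Or * e1)) # in (0, pi)
  L <- as.numeric(illuminator); o <- camera$nodal_point
  dpath <- function(psi) {
    u <- cos(psi) * e1 + sin(psi) * e2
    s <- c0 + R * u
    du <- R * (-sin(psi) * e1 + cos(psi) * e2)
    -(sum(unitize(L - s) * du) + sum(unitize(o - s) * du))
  }
  lo <- 1e-9; hi <- ang - 1e-9
  flo <- dpath(lo); fhi <- dpath(hi)
  if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0)
    sg_stop("no specular path in the camera-facing hemisphere", "stereogaze_no_glint")
  root <- uniroot(dpath, c(lo, hi), f.lower = flo, f.upper = fhi, tol = 1e-15)
  s <- c0 + R * (cos(root$root) * e1 + sin(root$root) * e2)
  if (sum((s - c0) * (o - s)) <= 0 || sum((s - c0) * (L - s)) <= 0)
    sg_stop("specular point not visible from camera and illuminator", "stereogaze_no_glint")
  px <- project_point(camera, s)
  attr(px, "surface_point") <- s
  px
}

#' Reflection-law residual at a corneal surface point (radians)
#'
#' Angle mismatch between incidence and reflection for the illuminator ->
#' surface -> camera path; a diagnostic for the glint solver.
#'
#' @inheritParams glint_pixel
#' @param surface_point the specular point returned by [glint_pixel()].
#' @return absolute angle mismatch, radians.
#' @export
reflection_residual <- function(eye, camera, illuminator, surface_point) {
  n <- unitize(surface_point - eye$corneal_center)
  vin <- unitize(as.numeric(illuminator) - surface_point)
  vout <- unitize(camera$nodal_point - surface_point)
  abs(acos(pmin(1, pmax(-1, sum(vin * n)))) -
        acos(pmin(1, pmax(-1, sum(vout * n)))))
}

#' Pupil-image pixel position
#'
#' In `no_refraction` mode the true pupil center is projected directly,
#' which makes the stereo inverse model exact (the basis of the round-trip
#' tests). In `snell` mode the chief ray is traced: the surface point on
#' the corneal sphere is found (1-D in-plane root-find) such that the ray
#' from the camera nodal point refracts at the anterior surface, per
#' Snell's law with the eye's refractive index, and passes through the
#' true pupil center; the camera then images the pupil along that ray, so
#' the pixel is the projection of the surface point. This displaces the
#' apparent (virtual) pupil from the true one, mainly in depth.
#'
#' @param eye an `eye_params`.
#' @param camera a `camera_model`.
#' @param mode `"no_refraction"` or `"snell"`.
#' @return length-2 pixel vector; in snell mode the attribute
#'   `surface_point` carries the corneal entry point.
#' @export
pupil_pixel <- function(eye, camera, mode = c("no_refraction", "snell")) {
  mode <- match.arg(mode)
  p <- pupil_center(eye)
  if (mode == "no_refraction") return(project_point(camera, p))
  c0 <- eye$corneal_center; R <- eye$corneal_radius
  o <- camera$nodal_point
  eta <- 1 / eye$refractive_index
  e1 <- unitize(o - c0)
  pr <- p - c0
  perp <- pr - sum(pr * e1) * e1
  if (sqrt(sum(perp^2)) < 1e-12 * max(1, sqrt(sum(pr^2)))) {
    # camera on the optical axis: chief ray travels along the axis unrefracted
    s <- c0 + R * e1
    px <- project_point(camera, s)
    attr(px, "surface_point") <- s
    return(px)
  }
  e2 <- unitize(perp)
  miss <- function(psi) {
    u <- cos(psi) * e1 + sin(psi) * e2
    s <- c0 + R * u
    di <- unitize(s - o)
    ci <- -sum(di * u)
    st2 <- eta^2 * (1 - ci^2)
    dt <- eta * di + (eta * ci - sqrt(1 - st2)) * u
    a <- p - s
    sum(a * e1) * sum(dt * e2) - sum(a * e2) * sum(dt * e1)
  }
  # robust bracketing: scan the camera-facing quarter-sphere for a sign change
  grid <- seq(1e-7, pi / 2 - 0.05, length.out = 60)
  vals <- vapply(grid, miss, numeric(1))
  sgn <- which(vals[-1] * vals[-length(vals)] <= 0)
  if (!length(sgn))
    sg_stop("no refracted chief ray reaches the pupil center", "stereogaze_numerical")
  root <- uniroot(miss, grid[c(sgn[1], sgn[1] + 1)], tol = 1e-15)
  s <- c0 + R * (cos(root$root) * e1 + sin(root$root) * e2)
  px <- project_point(camera, s)
  attr(px, "surface_point") <- s
  px
}

#' Render one pair of feature frames
#'
#' Computes the pupil pixel and both glint pixels for each camera, adds
#' isotropic Gaussian pixel noise, and flags the frame invalid when any
#' feature is off-sensor or no specular path exists.
#'
#' @param eye an `eye_params` (already positioned and oriented).
#' @param geometry a `system_geometry`.
#' @param pixel_noise_sd Gaussian pixel-noise SD, px.
#' @param mode pupil imaging mode, see [pupil_pixel()].
#' @param seed optional integer; when given, the RNG state is localized so
#'   identical seeds give identical noisy frames.
#' @return data.frame with one row per camera: `cam`, `pupil_x/y`,
#'   `glint1_x/y`, `glint2_x/y`, `valid`.
#' @export
render_features <- function(eye, geometry, pixel_noise_sd = 0,
                            mode = "no_refraction", seed = NULL) {
  with_seed_sg(seed, {
    rows <- lapply(1:2, function(k) {
      cam <- if (k == 1) geometry$camera1 else geometry$camera2
      feat <- tryCatch({
        pp <- pupil_pixel(eye, cam, mode)
        g1 <- glint_pixel(eye, cam, geometry$illuminator1)
        g2 <- glint_pixel(eye, cam, geometry$illuminator2)
        rbind(as.numeric(pp), as.numeric(g1), as.numeric(g2))
      }, stereogaze_error = function(e) NULL)
      if (is.null(feat))
        return(data.frame(cam = k, pupil_x = NA_real_, pupil_y = NA_real_,
                          glint1_x = NA_real_, glint1_y = NA_real_,
                          glint2_x = NA_real_, glint2_y = NA_real_, valid = FALSE))
      if (pixel_noise_sd > 0)
        feat <- feat + matrix(stats::rnorm(6, sd = pixel_noise_sd), 3, 2)
      ok <- all(feat[, 1] >= 0 & feat[, 1] <= cam$sensor_size[1] &
                  feat[, 2] >= 0 & feat[, 2] <= cam$sensor_size[2])
      data.frame(cam = k, pupil_x = feat[1, 1], pupil_y = feat[1, 2],
                 glint1_x = feat[2, 1], glint1_y = feat[2, 2],
                 glint2_x = feat[3, 1], glint2_y = feat[3, 2], valid = ok)
    })
    do.call(rbind, rows)
  })
}

#' The 54-target validation grid
#'
#' Targets at eccentricities 3, 6, 9 and 12 deg in twelve directions
#' (0:30:330) and at 15 deg in six directions (0, 45, 135, 180, 225, 315),
#' converted to screen millimeters through an imaginary eye on the screen
#' axis at the given viewing distance: radial distance =
#' `distance * tan(eccentricity)`.
#'
#' @param viewing_distance_mm imaginary-eye distance, mm.
#' @return data.frame with 54 rows: `x_mm`, `y_mm`, `ecc_deg`, `dir_deg`.
#' @export
target_grid <- function(viewing_distance_mm = 650) {
  ecc <- c(rep(c(3, 6, 9, 12), each = 12), rep(15, 6))
  dir <- c(rep(seq(0, 330, by = 30), times = 4), c(0, 45, 135, 180, 225, 315))
  r <- viewing_distance_mm * tan(ecc * pi / 180)
  data.frame(x_mm = r * cos(dir * pi / 180),
             y_mm = r * sin(dir * pi / 180),
             ecc_deg = ecc, dir_deg = dir)
}

#' Build a trial script
#'
#' Describes one simulated trial: an initial central fixation followed by
#' a saccade to the peripheral target at `target_onset_s`. Saccade
#' kinematics follow a raised-cosine velocity profile whose peak velocity
#' obeys the saturating main-sequence law
#' `v_peak = v0 * (1 - exp(-Amp / Amp0))`.
#'
#' @param target_xy_mm peripheral target, screen mm.
#' @param head_offset_mm rigid head translation from the nominal eye
#'   position, mm (tracker frame).
#' @param fixation_xy_mm initial fixation position, screen mm.
#' @param target_onset_s saccade go time, s.
#' @param duration_s total trial duration, s.
#' @param v0,Amp0 main-sequence parameters (deg/s, deg).
#' @param rate1_hz,rate2_hz nominal camera frame rates.
#' @param timing_jitter fractional uniform jitter on each frame interval.
#' @param pixel_noise_sd Gaussian pixel noise SD, px.
#' @param mode pupil imaging mode, see [pupil_pixel()].
#' @param seed integer RNG seed for all randomness in the trial.
#' @return a list of class `trial_script`.
#' @export
trial_script <- function(target_xy_mm, head_offset_mm = c(0, 0, 0),
                         fixation_xy_mm = c(0, 0), target_onset_s = 0.3,
                         duration_s = 0.8, v0 = 500, Amp0 = 5,
                         rate1_hz = 330, rate2_hz = 300,
                         timing_jitter = 0.1, pixel_noise_sd = 0,
                         mode = "no_refraction", seed = 1L) {
  if (rate1_hz <= 0 || rate2_hz <= 0)
    sg_stop("camera rates must be positive", "stereogaze_invalid_input")
  structure(list(target_xy_mm = as.numeric(target_xy_mm),
                 head_offset_mm = as.numeric(head_offset_mm),
                 fixation_xy_mm = as.numeric(fixation_xy_mm),
                 target_onset_s = target_onset_s, duration_s = duration_s,
                 v0 = v0, Amp0 = Amp0, rate1_hz = rate1_hz, rate2_hz = rate2_hz,
                 timing_jitter = timing_jitter, pixel_noise_sd = pixel_noise_sd,
                 mode = mode, seed = as.integer(seed)),
            class = "trial_script")
}

#' Raised-cosine saccade position profile (0..1)
#' @noRd
saccade_profile <- function(t_rel, duration) {
  x <- pmin(pmax(t_rel / duration, 0), 1)
  x - sin(2 * pi * x) / (2 * pi)
}

#' Visual-axis angles over a scripted trial
#' @noRd
script_angles <- function(script, t, ang_fix, ang_tgt) {
  amp <- sqrt(sum((ang_tgt - ang_fix)^2))
  if (amp < 1e-12) {
    return(matrix(ang_fix, length(t), 2, byrow = TRUE))
  }
  v_peak <- script$v0 * (1 - exp(-amp / script$Amp0))
  dur <- 2 * amp / v_peak
  frac <- saccade_profile(t - script$target_onset_s, dur)
  cbind(ang_fix[1] + frac * (ang_tgt[1] - ang_fix[1]),
        ang_fix[2] + frac * (ang_tgt[2] - ang_fix[2]))
}

#' Jittered camera timestamps for one trial
#' @noRd
camera_timestamps <- function(rate, jitter, duration) {
  n <- ceiling(duration * rate * 1.3) + 2
  dt <- (1 / rate) * (1 + stats::runif(n, -jitter, jitter))
  t <- stats::runif(1, 0, 1 / rate) + cumsum(c(0, dt))
  t[t <= duration]
}

#' Simulate one scripted trial
#'
#' The eye fixates the initial position, then makes a main-sequence
#' saccade to the peripheral target at the scripted onset. Both cameras
#' sample at independent jittered rates; each frame is rendered through
#' the forward eye model and perturbed with pixel noise. Ground truth
#' (true visual-axis angles and true point of gaze) is reported at every
#' camera timestamp.
#'
#' @param script a [trial_script()].
#' @param geometry a `system_geometry`.
#' @param eye an `eye_params`; its corneal center is taken as the nominal
#'   (central) position and displaced by the script's head offset.
#' @return list with `frames_cam1`, `frames_cam2` (feature-frame
#'   data.frames with `timestamp_s` and `eye = "right"`), and `truth`
#'   (data.frame `timestamp_s`, `cam`, `theta_true`, `phi_true`,
#'   `pog_x_mm`, `pog_y_mm`).
#' @export
simulate_trial <- function(script, geometry, eye) {
  stopifnot(inherits(script, "trial_script"))
  half_w <- geometry$screen_resolution[1] * geometry$pixel_pitch / 2
  half_h <- geometry$screen_resolution[2] * geometry$pixel_pitch / 2
  if (abs(script$target_xy_mm[1]) > half_w || abs(script$target_xy_mm[2]) > half_h)
    sg_stop("scripted target lies outside the screen", "stereogaze_invalid_input")
  eye$corneal_center <- eye$corneal_center + script$head_offset_mm
  ang_fix <- fixation_angles(eye, script$fixation_xy_mm, geometry)
  ang_tgt <- fixation_angles(eye, script$target_xy_mm, geometry)
  with_seed_sg(script$seed, {
    t1 <- camera_timestamps(script$rate1_hz, script$timing_jitter, script$duration_s)
    t2 <- camera_timestamps(script$rate2_hz, script$timing_jitter, script$duration_s)
    tt <- c(t1, t2)
    cam_of <- c(rep(1L, length(t1)), rep(2L, length(t2)))
    ang <- script_angles(script, tt, ang_fix, ang_tgt)
    # render unique orientations only (fixation phases share one pose)
    key <- paste(signif(ang[, 1], 15), signif(ang[, 2], 15))
    uk <- !duplicated(key)
    cache <- new.env(parent = emptyenv())
    for (i in which(uk)) {
      e <- orient_eye(eye, ang[i, 1], ang[i, 2], geometry)
      assign(key[i], render_features(e, geometry, pixel_noise_sd = 0,
                                     mode = script$mode), envir = cache)
    }
    feat <- lapply(seq_along(tt), function(i) {
      fr <- get(key[i], envir = cache)
      fr[fr$cam == cam_of[i], , drop = FALSE]
    })
    feat <- do.call(rbind, feat)
    if (script$pixel_noise_sd > 0) {
      cols <- c("pupil_x", "pupil_y", "glint1_x", "glint1_y", "glint2_x", "glint2_y")
      noise <- matrix(stats::rnorm(nrow(feat) * 6, sd = script$pixel_noise_sd),
                      nrow(feat), 6)
      feat[cols] <- feat[cols] + noise
      feat$valid <- feat$valid & stats::complete.cases(feat[cols])
    }
    feat$timestamp_s <- tt
    feat$eye <- "right"
    # ground truth POG from the true visual axis
    C <- to_screen_frame(eye$corneal_center, geometry)
    g <- cbind(cos(ang[, 2] * pi / 180) * sin(ang[, 1] * pi / 180),
               sin(ang[, 2] * pi / 180),
               -cos(ang[, 2] * pi / 180) * cos(ang[, 1] * pi / 180))
    lam <- C[3] / (cos(ang[, 2] * pi / 180) * cos(ang[, 1] * pi / 180))
    truth <- data.frame(timestamp_s = tt, cam = cam_of,
                        theta_true = ang[, 1], phi_true = ang[, 2],
                        pog_x_mm = C[1] + lam * g[, 1],
                        pog_y_mm = C[2] + lam * g[, 2])
    f1 <- feat[feat$cam == 1L, ]; f2 <- feat[feat$cam == 2L, ]
    list(frames_cam1 = f1[order(f1$timestamp_s), ],
         frames_cam2 = f2[order(f2$timestamp_s), ],
         truth = truth[order(truth$timestamp_s), ])
  })
}

#' Simulate a steady fixation
#'
#' Convenience wrapper around [simulate_trial()] for a static fixation of
#' a single target (no saccade), as used for one-point calibration and the
#' round-trip accuracy tests.
#'
#' @inheritParams simulate_trial
#' @param target_xy_mm fixated target, screen mm.
#' @param duration_s fixation duration, s.
#' @param ... passed through to [trial_script()] (noise, rates, mode,
#'   seed, head offset).
#' @return as [simulate_trial()].
#' @export
simulate_fixation <- function(target_xy_mm, geometry, eye, duration_s = 0.3, ...) {
  script <- trial_script(target_xy_mm = target_xy_mm,
                         fixation_xy_mm = target_xy_mm,
                         target_onset_s = 0, duration_s = duration_s, ...)
  simulate_trial(script, geometry, eye)
}
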