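# Rig description: two cameras, two IR illuminators, screen pose.
#
# Tracker frame convention: origin at the camera-1 nodal point, x/y
# parallel to its image plane, +z toward the participant. Screen (stimulus)
# frame: origin at the screen center, x horizontal, y vertical, +z out of
# the screen toward the participant; the physical screen surface is Z = 0.

#' Construct a system geometry
#'
#' Bundles the two calibrated cameras, the two illuminator positions, the
#' tracker-to-screen rigid transform and the screen's pixel metrics. The
#' screen transform maps tracker coordinates `p` to stimulus coordinates
#' via `P = screen_rotation %*% p + screen_translation`.
#'
#' @param camera1,camera2 `camera_model` objects (tracker frame).
#' @param illuminator1,illuminator2 length-3 illuminator positions, mm.
#' @param screen_rotation 3x3 orthonormal tracker-to-screen rotation.
#' @param screen_translation length-3 translation, mm (applied after the
#'   rotation).
#' @param screen_resolution length-2, pixels (width, height).
#' @param pixel_pitch pixel pitch, mm.
#' @return object of class `system_geometry`.
#' @export
system_geometry <- function(camera1, camera2, illuminator1, illuminator2,
                            screen_rotation = diag(3),
                            screen_translation = c(0, 0, 0),
                            screen_resolution = c(1920, 1200),
                            pixel_pitch = 0.27) {
  stopifnot(inherits(camera1, "camera_model"), inherits(camera2, "camera_model"))
  screen_rotation <- as.matrix(screen_rotation)
  if (!is_rotation_matrix(screen_rotation))
    sg_stop("screen_rotation must be orthonormal with det +1", "stereogaze_invalid_input")
  if (!is.numeric(pixel_pitch) || pixel_pitch <= 0)
    sg_stop("pixel_pitch must be positive", "stereogaze_invalid_input")
  structure(list(
    camera1 = camera1, camera2 = camera2,
    illuminator1 = as.numeric(illuminator1),
    illuminator2 = as.numeric(illuminator2),
    screen_rotation = screen_rotation,
    screen_translation = as.numeric(screen_translation),
    screen_resolution = as.numeric(screen_resolution),
    pixel_pitch = as.numeric(pixel_pitch)
  ), class = "system_geometry")
}

#' @export
print.system_geometry <- function(x, ...) {
  cat("<system_geometry>\n")
  cat(sprintf("  camera 1 nodal point: (%.1f, %.1f, %.1f) mm\n",
              x$camera1$nodal_point[1], x$camera1$nodal_point[2], x$camera1$nodal_point[3]))
  cat(sprintf("  camera 2 nodal point: (%.1f, %.1f, %.1f) mm\n",
              x$camera2$nodal_point[1], x$camera2$nodal_point[2], x$camera2$nodal_point[3]))
  cat(sprintf("  illuminators: (%.1f, %.1f, %.1f) / (%.1f, %.1f, %.1f) mm\n",
              x$illuminator1[1], x$illuminator1[2], x$illuminator1[3],
              x$illuminator2[1], x$illuminator2[2], x$illuminator2[3]))
  cat(sprintf("  screen: %d x %d px, pitch %.2f mm\n",
              x$screen_resolution[1], x$screen_resolution[2], x$pixel_pitch))
  invisible(x)
}

#' Map a tracker-frame point into the stimulus (screen) frame
#'
#' Applies the calibrated rigid transform: rotation, then translation. The
#' stimulus frame has the screen surface at Z = 0 and +Z toward the
#' participant, so a participant-facing eye has positive Z.
#'
#' @param p length-3 point (mm) or n x 3 matrix.
#' @param geometry a `system_geometry`.
#' @return transformed point(s), same shape as `p`.
#' @export
to_screen_frame <- function(p, geometry) {
  if (is.matrix(p))
    return(p %*% t(geometry$screen_rotation) +
             matrix(geometry$screen_translation, nrow(p), 3, byrow = TRUE))
  as.numeric(geometry$screen_rotation %*% as.numeric(p)) + geometry$screen_translation
}

#' Inverse of [to_screen_frame()]
#'
#' @inheritParams to_screen_frame
#' @return point(s) in tracker coordinates.
#' @export
from_screen_frame <- function(p, geometry) {
  if (is.matrix(p))
    return((p - matrix(geometry$screen_translation, nrow(p), 3, byrow = TRUE)) %*%
             geometry$screen_rotation)
  as.numeric(t(geometry$screen_rotation) %*%
               (as.numeric(p) - geometry$screen_translation))
}

#' Reference rig used throughout examples and tests
#'
#' A desk-scale stereo rig patterned after a tracker mounted on a rail
#' below the stimulus screen: two cameras 120 mm apart aimed at the
#' nominal eye position about 600 mm away, two IR illuminators flanking
#' them on the rail, and a 1920 x 1200 screen (0.27-mm pitch) whose center
#' sits 650 mm from the nominal eye. The tracker origin is the camera-1
#' nodal point; the nominal (central head position) eye is on the screen
#' axis.
#'
#' @param eye_position nominal corneal-center position in tracker
#'   coordinates, mm; head offsets in the simulator displace the eye from
#'   this point.
#' @param focal_length_px camera focal length, pixels (about an 8-mm lens
#'   at a 5.5-um pixel pitch).
#' @return a `system_geometry`.
#' @export
default_rig <- function(eye_position = c(60, 180, 600), focal_length_px = 1455) {
  sensor <- c(1048, 480)
  pp <- sensor / 2
  cam1 <- camera_model(c(0, 0, 0), look_at_rotation(c(0, 0, 0), eye_position),
                       focal_length_px, pp, sensor)
  cam2 <- camera_model(c(120, 0, 0), look_at_rotation(c(120, 0, 0), eye_position),
                       focal_length_px, pp, sensor)
  # screen plane at tracker z = -50, center directly "behind" the rail at
  # the nominal eye's x/y; the nominal eye is 650 mm from the screen center.
  system_geometry(
    cam1, cam2,
    illuminator1 = c(-40, 0, 0),
    illuminator2 = c(160, 0, 0),
    screen_rotation = diag(3),
    screen_translation = c(-eye_position[1], -eye_position[2], 50),
    screen_resolution = c(1920, 1200),
    pixel_pitch = 0.27
  )
}

#' Nominal viewing distance of the reference rig, mm
#' @noRd
default_viewing_distance <- function() 650
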