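# Mirror-based localization of hidden rig components. The illuminators and
# the screen cannot be seen directly by the tracker cameras, so a planar
# front-surface mirror carrying a dot pattern is placed in front of the
# rig: the cameras triangulate (i) the mirror markers directly, giving the
# mirror plane, and (ii) the virtual images of the illuminators and of a
# dot pattern displayed on the screen, which reflecting across the fitted
# plane converts into real-world positions.

#' Fit the calibration-mirror plane
#'
#' Triangulates each marker from its pixel coordinates in the two cameras
#' and fits a total-least-squares plane (SVD of the centered point cloud)
#' through the reconstructed 3-D markers.
#'
#' @param markers data.frame with columns `px1_x, px1_y, px2_x, px2_y`
#'   (pixel coordinates of each marker in cameras 1 and 2), one row per
#'   marker. At least 3 non-collinear markers are required.
#' @param geometry a `system_geometry` (only the cameras are used).
#' @return a `plane3`; attributes `rms_mm` (RMS point-to-plane distance)
#'   and `points` (the triangulated n x 3 marker cloud).
#' @export
fit_mirror_plane <- function(markers, geometry) {
  if (nrow(markers) < 3L)
    sg_stop("mirror-plane fit needs at least 3 markers", "stereogaze_calibration_error")
  pts <- t(vapply(seq_len(nrow(markers)), function(i) {
    triangulate_rays(
      back_project(geometry$camera1, c(markers$px1_x[i], markers$px1_y[i])),
      back_project(geometry$camera2, c(markers$px2_x[i], markers$px2_y[i]))
    )$point
  }, numeric(3)))
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2, ctr))
  # collinear cloud: second singular value vanishes relative to the first
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1))
    sg_stop("mirror markers are collinear; plane fit is degenerate",
            "stereogaze_calibration_error")
  normal <- sv$v[, 3]
  rms <- sqrt(mean((sweep(pts, 2, ctr) %*% normal)^2))
  pl <- plane3(ctr, normal)
  attr(pl, "rms_mm") <- rms
  attr(pl, "points") <- pts
  pl
}

#' Localize a hidden point from its mirror image
#'
#' Triangulates the virtual image seen in the mirror from its pixel
#' coordinates in both cameras, then reflects the triangulated point
#' across the mirror plane to obtain the real-world position. Used for the
#' IR illuminators and for screen dots, neither of which the cameras can
#' see directly.
#'
#' @param px_cam1,px_cam2 length-2 pixel coordinates of the virtual image.
#' @param mirror the fitted `plane3`.
#' @param geometry a `system_geometry`.
#' @return length-3 position, mm, tracker frame.
#' @export
localize_hidden_point <- function(px_cam1, px_cam2, mirror, geometry) {
  virt <- triangulate_rays(back_project(geometry$camera1, px_cam1),
                           back_project(geometry$camera2, px_cam2))$point
  reflect_point(virt, mirror)
}

#' Fit the screen pose from mirrored dot observations
#'
#' Reconstructs each displayed dot's real-world position via
#' [localize_hidden_point()] and solves the orthogonal Procrustes (Kabsch)
#' problem mapping the tracker-frame reconstructions onto the dots' known
#' stimulus-frame positions `(x, y, 0)`.
#'
#' @param dots data.frame with columns `px1_x, px1_y, px2_x, px2_y`
#'   (pixels of each dot's virtual image in the two cameras) and
#'   `layout_x_mm, layout_y_mm` (the dot's position on the screen,
#'   stimulus frame, mm).
#' @param mirror fitted mirror `plane3`.
#' @param geometry a `system_geometry`.
#' @return list with `screen_rotation` (3x3), `screen_translation`
#'   (length-3) and `rms_mm`; the transform satisfies
#'   `R %*% p + T = (layout_x, layout_y, 0)` in the least-squares sense.
#' @export
fit_screen_pose <- function(dots, mirror, geometry) {
  if (nrow(dots) < 3L)
    sg_stop("screen-pose fit needs at least 3 dots", "stereogaze_calibration_error")
  X <- t(vapply(seq_len(nrow(dots)), function(i) {
    localize_hidden_point(c(dots$px1_x[i], dots$px1_y[i]),
                          c(dots$px2_x[i], dots$px2_y[i]), mirror, geometry)
  }, numeric(3)))
  Y <- cbind(dots$layout_x_mm, dots$layout_y_mm, 0)
  sv <- svd(crossprod(sweep(X, 2, colMeans(X)), sweep(Y, 2, colMeans(Y))))
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1))
    sg_stop("screen dots are collinear; pose fit is degenerate",
            "stereogaze_calibration_error")
  R <- sv$v %*% diag(c(1, 1, det(sv$v %*% t(sv$u)))) %*% t(sv$u)
  T <- colMeans(Y) - as.numeric(R %*% colMeans(X))
  resid <- Y - (X %*% t(R) + matrix(T, nrow(X), 3, byrow = TRUE))
  list(screen_rotation = R, screen_translation = T,
       rms_mm = sqrt(mean(rowSums(resid^2))))
}

#' Run the full mirror calibration against simulated observations
#'
#' Convenience wrapper tying the three steps together: fit the mirror
#' plane from direct marker views, localize both illuminators from their
#' virtual images, and fit the screen pose from mirrored screen dots.
#' Residuals of every stage are reported in the returned object and via
#' `message()` so that calibration quality is always surfaced.
#'
#' @param markers marker observations for [fit_mirror_plane()].
#' @param illum_px list of two lists, each with `px_cam1`, `px_cam2` for
#'   one illuminator's virtual image.
#' @param dots screen-dot observations for [fit_screen_pose()].
#' @param geometry a `system_geometry` holding the calibrated cameras; its
#'   illuminator and screen fields are replaced by the fitted values.
#' @param quiet suppress the residual report message.
#' @return a new `system_geometry` with fitted illuminators and screen
#'   pose; attribute `report` holds the per-stage RMS residuals.
#' @export
calibrate_system <- function(markers, illum_px, dots, geometry, quiet = FALSE) {
  mirror <- fit_mirror_plane(markers, geometry)
  L1 <- localize_hidden_point(illum_px[[1]]$px_cam1, illum_px[[1]]$px_cam2, mirror, geometry)
  L2 <- localize_hidden_point(illum_px[[2]]$px_cam1, illum_px[[2]]$px_cam2, mirror, geometry)
  pose <- fit_screen_pose(dots, mirror, geometry)
  out <- system_geometry(geometry$camera1, geometry$camera2, L1, L2,
                         pose$screen_rotation, pose$screen_translation,
                         geometry$screen_resolution, geometry$pixel_pitch)
  report <- c(mirror_rms_mm = attr(mirror, "rms_mm"), screen_rms_mm = pose$rms_mm)
  if (!quiet)
    message(sprintf("system calibration: mirror-plane RMS %.2e mm, screen-pose RMS %.2e mm",
                    report[1], report[2]))
  attr(out, "report") <- report
  out
}
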