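# 3-D primitives: rays, planes, least-squares two-line intersection,
# mirror reflection, pinhole projection. All lengths in mm, angles in
# degrees at API boundaries (radians internally).

#' Internal condition helper
#' @noRd
sg_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "stereogaze_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' Normalize a vector to unit length
#' @noRd
unitize <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < .Machine$double.eps) sg_stop("cannot normalize zero-length vector", "stereogaze_degenerate")
  v / n
}

#' Construct a 3-D ray
#'
#' A ray is a half-infinite line with an `origin` (mm) and a unit
#' `direction`. Directions are renormalized on construction.
#'
#' @param origin numeric length-3, mm.
#' @param direction numeric length-3; need not be unit length on input.
#' @return An object of class `ray3` with fields `origin` and `direction`
#'   (unit norm).
#' @export
ray3 <- function(origin, direction) {
  origin <- as.numeric(origin)
  if (length(origin) != 3L || !all(is.finite(origin)))
    sg_stop("ray origin must be 3 finite numbers", "stereogaze_invalid_input")
  d <- unitize(as.numeric(direction))
  structure(list(origin = origin, direction = d), class = "ray3")
}

#' @export
print.ray3 <- function(x, ...) {
  cat(sprintf("<ray3> origin (%.3f, %.3f, %.3f) mm, direction (%.6f, %.6f, %.6f)\n",
              x$origin[1], x$origin[2], x$origin[3],
              x$direction[1], x$direction[2], x$direction[3]))
  invisible(x)
}

#' Construct a 3-D plane
#'
#' @param point any point on the plane, mm.
#' @param normal plane normal; renormalized to unit length.
#' @return An object of class `plane3`.
#' @export
plane3 <- function(point, normal) {
  point <- as.numeric(point)
  if (length(point) != 3L || !all(is.finite(point)))
    sg_stop("plane point must be 3 finite numbers", "stereogaze_invalid_input")
  structure(list(point = point, normal = unitize(as.numeric(normal))), class = "plane3")
}

#' Least-squares intersection of two 3-D lines
#'
#' Solves for the closest point between the two (infinite) lines carrying
#' the rays: the parameters of the shortest connecting segment come from
#' the closed-form 2x2 normal equations, and the returned point is the
#' segment midpoint. For truly intersecting lines the residual (segment
#' length) is zero; skew lines triangulate to the midpoint with a positive
#' residual. This is the primitive behind every 3-D reconstruction in the
#' package: the virtual pupil from the two pupil images, the virtual
#' illuminator images from the glints, and the corneal-curvature center
#' from the two illuminator axes.
#'
#' @param ray_a,ray_b `ray3` objects.
#' @return list with `point` (length-3, mm) and `residual_mm` (shortest
#'   distance between the lines).
#' @section Errors: near-parallel rays (|cos angle| >= 1 - 1e-9) signal a
#'   `stereogaze_degenerate` error; such geometry indicates corrupt input
#'   rather than a recoverable measurement.
#' @export
triangulate_rays <- function(ray_a, ray_b) {
  da <- ray_a$direction; db <- ray_b$direction
  d <- sum(da * db)
  if (abs(d) >= 1 - 1e-9)
    sg_stop("rays are parallel or nearly parallel; triangulation is degenerate",
            "stereogaze_degenerate")
  w <- ray_b$origin - ray_a$origin
  # minimize |oa + t da - (ob + s db)|^2 over (t, s)
  # normal equations: [1 -d; d -1] [t; s] = [w.da; w.db]
  det <- d * d - 1
  wa <- sum(w * da); wb <- sum(w * db)
  t <- (-wa + d * wb) / det
  s <- (-d * wa + wb) / det
  pa <- ray_a$origin + t * da
  pb <- ray_b$origin + s * db
  list(point = (pa + pb) / 2, residual_mm = sqrt(sum((pa - pb)^2)))
}

#' Reflect a point across a plane
#'
#' Standard mirror geometry: the image of `p` lies on the opposite side of
#' the plane at equal distance. Used to recover real illuminator and
#' screen-dot positions from their virtual images behind the calibration
#' mirror. Reflection is an involution: reflecting twice restores the
#' input.
#'
#' @param p numeric length-3, mm.
#' @param mirror a `plane3`.
#' @return the mirrored point (length-3, mm).
#' @export
reflect_point <- function(p, mirror) {
  p <- as.numeric(p)
  n <- mirror$normal
  p - 2 * sum((p - mirror$point) * n) * n
}

#' Construct a pinhole camera model
#'
#' The camera frame is related to the tracker frame by
#' `p_cam = rotation %*% (p - nodal_point)`; points with positive camera-z
#' are in front of the camera. Projection is the usual perspective model
#' `pixel = principal_point + focal_length * (x/z, y/z)`.
#'
#' @param nodal_point camera nodal point in tracker coordinates, mm.
#' @param rotation 3x3 orthonormal tracker-to-camera rotation (det +1).
#' @param focal_length focal length in pixels.
#' @param principal_point length-2 principal point, pixels.
#' @param sensor_size length-2 sensor size (width, height), pixels.
#' @return object of class `camera_model`.
#' @export
camera_model <- function(nodal_point, rotation, focal_length,
                         principal_point, sensor_size) {
  rotation <- as.matrix(rotation)
  if (!is_rotation_matrix(rotation))
    sg_stop("camera rotation must be orthonormal with det +1", "stereogaze_invalid_input")
  if (!is.numeric(focal_length) || focal_length <= 0)
    sg_stop("focal length must be positive", "stereogaze_invalid_input")
  structure(list(
    nodal_point = as.numeric(nodal_point),
    rotation = rotation,
    focal_length = as.numeric(focal_length),
    principal_point = as.numeric(principal_point),
    sensor_size = as.numeric(sensor_size)
  ), class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf("<camera_model> nodal point (%.1f, %.1f, %.1f) mm, f = %.1f px, pp = (%.1f, %.1f), sensor %d x %d px\n",
              x$nodal_point[1], x$nodal_point[2], x$nodal_point[3],
              x$focal_length, x$principal_point[1], x$principal_point[2],
              x$sensor_size[1], x$sensor_size[2]))
  invisible(x)
}

#' Test a matrix for being a proper rotation
#' @noRd
is_rotation_matrix <- function(R, tol = 1e-10) {
  is.matrix(R) && all(dim(R) == c(3L, 3L)) &&
    max(abs(crossprod(R) - diag(3))) < tol && abs(det(R) - 1) < tol
}

#' Project a 3-D point into camera pixels
#'
#' @param cam a `camera_model`.
#' @param p length-3 point (mm, tracker frame) or an n x 3 matrix of points.
#' @return length-2 pixel vector, or n x 2 matrix when `p` is a matrix.
#' @section Errors: points at or behind the nodal plane signal
#'   `stereogaze_projection_error`.
#' @export
project_point <- function(cam, p) {
  if (is.matrix(p)) {
    pc <- (p - matrix(cam$nodal_point, nrow(p), 3, byrow = TRUE)) %*% t(cam$rotation)
    if (any(pc[, 3] <= 1e-9))
      sg_stop("point at or behind the camera nodal plane", "stereogaze_projection_error")
    px <- cbind(cam$principal_point[1] + cam$focal_length * pc[, 1] / pc[, 3],
                cam$principal_point[2] + cam$focal_length * pc[, 2] / pc[, 3])
    return(px)
  }
  pc <- as.numeric(cam$rotation %*% (as.numeric(p) - cam$nodal_point))
  if (pc[3] <= 1e-9)
    sg_stop("point at or behind the camera nodal plane", "stereogaze_projection_error")
  cam$principal_point + cam$focal_length * pc[1:2] / pc[3]
}

#' Back-project a pixel to a 3-D viewing ray
#'
#' Returns the ray from the camera nodal point through the given pixel;
#' the inverse of [project_point()] up to the (unobservable) depth.
#'
#' @param cam a `camera_model`.
#' @param px length-2 pixel coordinates.
#' @return a `ray3` with origin at the nodal point.
#' @export
back_project <- function(cam, px) {
  px <- as.numeric(px)
  if (length(px) != 2L || !all(is.finite(px)))
    sg_stop("pixel must be 2 finite numbers", "stereogaze_invalid_input")
  d_cam <- c((px - cam$principal_point) / cam$focal_length, 1)
  ray3(cam$nodal_point, as.numeric(t(cam$rotation) %*% d_cam))
}

#' Look-at rotation for a camera
#'
#' Builds the tracker-to-camera rotation of a camera at `from` whose
#' optical axis points toward `at`, with the image x-axis as horizontal as
#' the `up` hint allows.
#'
#' @param from camera nodal point, mm.
#' @param at point the optical axis passes through, mm.
#' @param up approximate image up direction in tracker coordinates.
#' @return 3x3 rotation matrix suitable for [camera_model()].
#' @export
look_at_rotation <- function(from, at, up = c(0, 1, 0)) {
  z <- unitize(as.numeric(at) - as.numeric(from))
  x <- unitize(pracma_cross(as.numeric(up), z))
  y <- pracma_cross(z, x)
  R <- rbind(x, y, z)
  dimnames(R) <- NULL
  R
}

#' Cross product
#' @noRd
pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
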