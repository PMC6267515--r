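# Desk-scale counterpart of the tracker's online image processing:
# synthetic eye rasters (dark elliptical pupil on a mid-gray iris, bright
# glint spots) and subpixel feature extraction by threshold segmentation,
# least-squares ellipse fitting of the pupil contour, and
# intensity-weighted glint centroids.
#
# Pixel coordinate convention: x runs along columns, y along rows, both
# 1-based, with integer coordinates at pixel centers.

#' Segmentation configuration
#'
#' @param pupil_threshold intensity below which pixels are pupil
#'   candidates.
#' @param glint_threshold intensity above which pixels are glint
#'   candidates.
#' @param pupil_size_bounds,glint_size_bounds accepted component areas,
#'   px.
#' @return list of class `seg_config`.
#' @export
seg_config <- function(pupil_threshold = 70, glint_threshold = 200,
                       pupil_size_bounds = c(40, 8000),
                       glint_size_bounds = c(2, 400)) {
  if (pupil_threshold < 0 || pupil_threshold > 255 ||
      glint_threshold < 0 || glint_threshold > 255)
    sg_stop("thresholds must lie in [0, 255]", "stereogaze_invalid_input")
  if (pupil_size_bounds[1] >= pupil_size_bounds[2] ||
      glint_size_bounds[1] >= glint_size_bounds[2] ||
      any(c(pupil_size_bounds, glint_size_bounds) < 0))
    sg_stop("size bounds must be positive with min < max", "stereogaze_invalid_input")
  structure(list(pupil_threshold = pupil_threshold,
                 glint_threshold = glint_threshold,
                 pupil_size_bounds = pupil_size_bounds,
                 glint_size_bounds = glint_size_bounds),
            class = "seg_config")
}

#' Render a synthetic eye raster
#'
#' Draws an anti-aliased dark ellipse (the pupil) on a mid-gray iris
#' background plus small bright Gaussian spots at the glint positions,
#' then adds Gaussian intensity noise. Anti-aliasing is by 3x3
#' supersampled coverage. Deterministic for a given seed.
#'
#' @param pupil list with `center` (length-2, px), `semi_axes` (length-2,
#'   px) and `tilt_deg` (ellipse rotation).
#' @param glints n x 2 matrix of glint centers, px.
#' @param size raster size `c(width, height)`, px.
#' @param noise_sd Gaussian intensity-noise SD (8-bit units).
#' @param seed optional RNG seed (localized).
#' @param background,pupil_level,glint_amplitude,glint_sigma rendering
#'   intensities and glint spot width.
#' @return numeric matrix (rows = height, cols = width) of intensities in
#'   [0, 255]; attribute `ground_truth` records the feature parameters.
#' @export
render_eye_raster <- function(pupil, glints, size = c(160, 120),
                              noise_sd = 0, seed = NULL,
                              background = 128, pupil_level = 25,
                              glint_amplitude = 170, glint_sigma = 1.3) {
  w <- size[1]; h <- size[2]
  if (any(pupil$center < 1) || pupil$center[1] > w || pupil$center[2] > h)
    sg_stop("pupil center outside the raster", "stereogaze_invalid_input")
  ss <- 3
  # supersampled grid: ss subsamples per pixel, centered on the pixel
  sub <- (seq_len(ss) - (ss + 1) / 2) / ss
  cov <- matrix(0, h, w)
  ct <- cos(pupil$tilt_deg * pi / 180); st <- sin(pupil$tilt_deg * pi / 180)
  a <- pupil$semi_axes[1]; b <- pupil$semi_axes[2]
  for (dy in sub) for (dx in sub) {
    X <- outer(rep(1, h), seq_len(w) + dx) - pupil$center[1]
    Y <- outer(seq_len(h) + dy, rep(1, w)) - pupil$center[2]
    U <- (X * ct + Y * st) / a
    V <- (-X * st + Y * ct) / b
    cov <- cov + (U * U + V * V <= 1)
  }
  cov <- cov / (ss * ss)
  img <- background + (pupil_level - background) * cov
  if (!is.null(glints) && nrow(as.matrix(glints)) > 0) {
    glints <- as.matrix(glints)
    X <- outer(rep(1, h), seq_len(w))
    Y <- outer(seq_len(h), rep(1, w))
    for (i in seq_len(nrow(glints))) {
      img <- img + glint_amplitude *
        exp(-((X - glints[i, 1])^2 + (Y - glints[i, 2])^2) / (2 * glint_sigma^2))
    }
  }
  img <- with_seed_sg(seed, {
    if (noise_sd > 0) img + matrix(stats::rnorm(h * w, sd = noise_sd), h, w) else img
  })
  img <- pmin(pmax(img, 0), 255)
  attr(img, "ground_truth") <- list(pupil = pupil, glints = glints)
  img
}

#' Connected-component labeling (8-connectivity)
#'
#' EBImage::bwlabel does the 4-connected labeling; components touching
#' only diagonally are then merged with a union-find pass so that the
#' result is 8-connected.
#' @noRd
label_components <- function(mask) {
  lab <- t(EBImage::imageData(EBImage::bwlabel(t(mask) * 1))) # EBImage is x-major
  nlab <- max(lab)
  if (nlab < 2) return(lab)
  parent <- seq_len(nlab)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  h <- nrow(lab); w <- ncol(lab)
  for (off in list(c(1, 1), c(1, -1))) {
    a <- lab[1:(h - 1), if (off[2] > 0) 1:(w - 1) else 2:w]
    b <- lab[2:h, if (off[2] > 0) 2:w else 1:(w - 1)]
    touch <- which(a > 0 & b > 0 & a != b)
    for (k in touch) {
      ra <- find(a[k]); rb <- find(b[k])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(nlab), find, integer(1))
  dense <- match(roots, sort(unique(roots)))
  lab[lab > 0] <- dense[lab[lab > 0]]
  lab
}

#' Extract the pupil from an eye raster
#'
#' Thresholds the raster from below, keeps the largest 8-connected dark
#' component whose area is inside the configured bounds, and fits a
#' direct least-squares ellipse to the component's contour pixels; the
#' ellipse center is the subpixel pupil estimate.
#'
#' @param raster intensity matrix from [render_eye_raster()] or
#'   [read_eye_raster()].
#' @param config a [seg_config()].
#' @return list with `center` (length-2 px), `semi_axes`, `tilt_deg`,
#'   `area_px`.
#' @section Errors: `stereogaze_not_found` when no qualifying component
#'   exists.
#' @export
extract_pupil <- function(raster, config) {
  lab <- label_components(raster < config$pupil_threshold)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= config$pupil_size_bounds[1] &
                  sizes <= config$pupil_size_bounds[2])
  if (!length(keep))
    sg_stop("no pupil-sized dark component found", "stereogaze_not_found")
  id <- keep[which.max(sizes[keep])]
  comp <- lab == id
  # contour: component pixels with a 4-neighbor outside the component
  pad <- rbind(FALSE, cbind(FALSE, comp, FALSE), FALSE)
  h <- nrow(comp); w <- ncol(comp)
  core <- pad[2:(h + 1), 2:(w + 1)]
  interior <- core & pad[1:h, 2:(w + 1)] & pad[3:(h + 2), 2:(w + 1)] &
    pad[2:(h + 1), 1:w] & pad[2:(h + 1), 3:(w + 2)]
  contour <- which(core & !interior, arr.ind = TRUE)
  fit <- fit_ellipse_lsq(contour[, 2], contour[, 1])
  list(center = fit$center, semi_axes = fit$semi_axes,
       tilt_deg = fit$tilt_deg, area_px = sizes[id])
}

#' Direct least-squares ellipse fit (conic with ellipse constraint)
#'
#' Fits the conic `Ax^2 + Bxy + Cy^2 + Dx + Ey + F = 0` subject to the
#' ellipse constraint `4AC - B^2 = 1` by the partitioned generalized
#' eigenproblem, and converts to center / semi-axes / tilt.
#'
#' @param x,y contour coordinates, px.
#' @return list: `center`, `semi_axes` (major, minor), `tilt_deg`,
#'   `conic` (A..F).
#' @export
fit_ellipse_lsq <- function(x, y) {
  if (length(x) < 5)
    sg_stop("ellipse fit needs at least 5 points", "stereogaze_not_found")
  mx <- mean(x); my <- mean(y)
  xs <- x - mx; ys <- y - my
  D1 <- cbind(xs^2, xs * ys, ys^2)
  D2 <- cbind(xs, ys, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  Tm <- -solve(S3, t(S2))
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  evec <- Re(ev$vectors)
  cond <- 4 * evec[1, ] * evec[3, ] - evec[2, ]^2
  k <- which(cond > 0)
  if (!length(k))
    sg_stop("no ellipse solution for the contour", "stereogaze_not_found")
  a1 <- evec[, k[1]]
  coefs <- c(a1, as.numeric(Tm %*% a1)) # A B C D E F in centered coords
  A <- coefs[1]; B <- coefs[2]; C <- coefs[3]
  D <- coefs[4]; E <- coefs[5]; F <- coefs[6]
  den <- 4 * A * C - B^2
  xc <- (B * E - 2 * C * D) / den
  yc <- (B * D - 2 * A * E) / den
  F0 <- F + A * xc^2 + B * xc * yc + C * yc^2 + D * xc + E * yc
  Mq <- matrix(c(A, B / 2, B / 2, C), 2)
  lam <- eigen(Mq, symmetric = TRUE)$values # decreasing
  axes <- sqrt(pmax(-F0 / lam, 0)) # larger eigenvalue -> minor axis
  tilt <- 0.5 * atan2(B, A - C) * 180 / pi
  list(center = c(xc + mx, yc + my),
       semi_axes = sort(axes, decreasing = TRUE),
       tilt_deg = tilt,
       conic = c(A = A, B = B, C = C, D = D, E = E, F = F))
}

#' Extract glint centers from an eye raster
#'
#' Thresholds from above, keeps 8-connected bright components within the
#' configured area bounds, and returns the intensity-weighted centroid of
#' each, sorted left to right.
#'
#' @inheritParams extract_pupil
#' @return n x 2 matrix of centers (px), zero rows when none found.
#' @export
extract_glints <- function(raster, config) {
  lab <- label_components(raster > config$glint_threshold)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= config$glint_size_bounds[1] &
                  sizes <= config$glint_size_bounds[2])
  if (!length(keep)) return(matrix(numeric(0), 0, 2))
  centers <- t(vapply(keep, function(id) {
    idx <- which(lab == id, arr.ind = TRUE)
    # above-threshold excess as weight: removes the pedestal bias a constant
    # background adds to the centroid of an asymmetrically cropped spot
    wgt <- raster[idx] - config$glint_threshold
    c(sum(idx[, 2] * wgt), sum(idx[, 1] * wgt)) / sum(wgt)
  }, numeric(2)))
  centers[order(centers[, 1]), , drop = FALSE]
}

#' Pupil-glint vector
#'
#' Componentwise difference between the pupil center and a glint center;
#' the quantity shown as online feedback in pupil/CR trackers and
#' invariant to whole-image translation.
#'
#' @param pupil_center,glint_center length-2 pixel positions.
#' @return length-2 vector, px.
#' @export
pupil_glint_vector <- function(pupil_center, glint_center) {
  as.numeric(pupil_center) - as.numeric(glint_center)
}

#' Read an 8-bit grayscale eye raster from PNG
#'
#' @param path PNG file path.
#' @return intensity matrix in [0, 255].
#' @export
read_eye_raster <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img * 255
}

#' Write an eye raster to 8-bit grayscale PNG
#'
#' @param raster intensity matrix in [0, 255].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_eye_raster <- function(raster, path) {
  png::writePNG(pmin(pmax(raster / 255, 0), 1), path)
  invisible(path)
}
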