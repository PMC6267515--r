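# Inverse-model checks: synchronization, the K depth constraint, angle
# extraction, screen intersection, the K-gain correction, the median
# filter, and full round trips against the forward simulator.

test_that("synchronization is the identity on shared timestamp grids", {
  f <- data.frame(timestamp_s = seq(0, 1, by = 0.01),
                  pupil_x = sin(seq(0, 1, by = 0.01)), pupil_y = 5,
                  glint1_x = 1, glint1_y = 1, glint2_x = 2, glint2_y = 2,
                  valid = TRUE)
  s <- synchronize_frames(f, f)
  expect_equal(nrow(s), 2 * nrow(f))
  expect_equal(s$pupil_x_1, s$pupil_x_2)
  expect_true(all(s$valid))
})

test_that("midway samples interpolate linearly moving features exactly", {
  t1 <- seq(0, 1, by = 0.1)
  f1 <- data.frame(timestamp_s = t1, pupil_x = 100 * t1, pupil_y = 5,
                   glint1_x = 1, glint1_y = 1, glint2_x = 2, glint2_y = 2,
                   valid = TRUE)
  f2 <- f1; f2$timestamp_s <- t1 + 0.05; f2$pupil_x <- 100 * f2$timestamp_s
  s <- synchronize_frames(f1, f2)
  own1 <- s$source_cam == 1 & s$valid
  expect_equal(s$pupil_x_2[own1], 100 * s$timestamp_s[own1], tolerance = 1e-12)
})

test_that("interpolation never bridges long invalid gaps", {
  t1 <- seq(0, 1, by = 0.1)
  f1 <- data.frame(timestamp_s = t1, pupil_x = 1, pupil_y = 1,
                   glint1_x = 1, glint1_y = 1, glint2_x = 2, glint2_y = 2,
                   valid = TRUE)
  f2 <- f1
  f2$valid[4:6] <- FALSE # three consecutive dropped frames
  s <- synchronize_frames(f1, f2)
  mid <- s$source_cam == 1 & s$timestamp_s > 0.3 & s$timestamp_s < 0.5
  expect_false(any(s$valid[mid]))
})

test_that("disjoint time ranges give an empty synchronization with a warning", {
  f1 <- data.frame(timestamp_s = 0:1, pupil_x = 1, pupil_y = 1,
                   glint1_x = 1, glint1_y = 1, glint2_x = 2, glint2_y = 2,
                   valid = TRUE)
  f2 <- f1; f2$timestamp_s <- f2$timestamp_s + 10
  expect_warning(s <- synchronize_frames(f1, f2), "overlap")
  expect_equal(nrow(s), 0)
})

test_that("asynchronous streams synchronize at the summed rate", {
  geo <- test_rig(); eye <- test_eye()
  sim <- simulate_fixation(c(0, 0), geo, eye, duration_s = 0.5,
                           rate1_hz = 330, rate2_hz = 300, seed = 21)
  s <- synchronize_frames(sim$frames_cam1, sim$frames_cam2)
  n_in <- nrow(sim$frames_cam1) + nrow(sim$frames_cam2)
  expect_gte(nrow(s), n_in - 4) # minus edge records outside the overlap
  expect_lte(nrow(s), n_in)
})

test_that("a smooth pursuit-like trace reconstructs within 0.05 deg", {
  geo <- test_rig(); eye <- test_eye()
  calib <- test_calibration()
  th_fun <- function(t) 5 * sin(2 * pi * 0.5 * t)
  ph_fun <- function(t) 2 * cos(2 * pi * 0.5 * t)
  set.seed(31)
  t1 <- seq(0.001, 0.5, by = 1 / 330) + stats::runif(165, -1e-4, 1e-4)[1]
  t2 <- seq(0.0025, 0.5, by = 1 / 300)
  f1 <- render_stream(t1, th_fun, ph_fun, geo, eye)
  f2 <- render_stream(t2, th_fun, ph_fun, geo, eye)
  g <- reconstruct_gaze(f1[f1$cam == 1, ], f2[f2$cam == 2, ], geo, calib,
                        filter_width = 1)
  use <- g$valid
  err_th <- g$theta_corr[use] - th_fun(g$timestamp_s[use])
  err_ph <- g$phi_corr[use] - ph_fun(g$timestamp_s[use])
  expect_lt(max(abs(err_th)), 0.05)
  expect_lt(max(abs(err_ph)), 0.05)
})

test_that("the K constraint keeps x/y and solves the depth exactly", {
  expect_equal(apply_k_constraint(c(0, 0, 0), c(0, 0, -4.1), 5), c(0, 0, -5))
  pk <- apply_k_constraint(c(0, 0, 0), c(1, 0, -10), 5)
  expect_equal(pk, c(1, 0, -sqrt(24)))
  expect_error(apply_k_constraint(c(0, 0, 0), c(6, 0, -3), 5),
               class = "stereogaze_invalid_sample")
  # |p' - c| = K exactly, over random geometry
  set.seed(41)
  for (i in 1:25) {
    cc <- stats::rnorm(3, sd = 20)
    pv <- cc + c(stats::rnorm(2, sd = 2), -stats::runif(1, 3, 8))
    K <- sqrt(sum((pv - cc)^2)) * stats::runif(1, 1, 1.3)
    pk <- apply_k_constraint(cc, pv, K)
    expect_equal(sqrt(sum((pk - cc)^2)), K, tolerance = 1e-12)
    expect_equal(pk[1:2], pv[1:2])
    expect_lt(pk[3], cc[3]) # pupil on the camera side
  }
})

test_that("optical-axis angles follow the pan/tilt parameterization", {
  expect_equal(optical_axis_angles(c(0, 0, 0), c(0, 0, -1)), c(theta = 0, phi = 0))
  a <- optical_axis_angles(c(0, 0, 0), c(0.5, 0, -sqrt(1 - 0.25)))
  expect_equal(as.numeric(a), c(30, 0), tolerance = 1e-9)
  a <- optical_axis_angles(c(0, 0, 0), c(0, 0.5, -sqrt(1 - 0.25)))
  expect_equal(as.numeric(a), c(0, 30), tolerance = 1e-9)
  expect_error(optical_axis_angles(c(1, 2, 3), c(1, 2, 3)),
               class = "stereogaze_invalid_sample")
})

test_that("the gaze ray intersects the screen plane where expected", {
  calib0 <- structure(list(alpha = 0, beta = 0, K = 4.2),
                      class = "gaze_calibration")
  res <- point_of_gaze(c(0, 0, 650), 0, 0, calib0)
  expect_equal(res$lambda_g, 650)
  expect_equal(res$pog, c(0, 0))
  expect_equal(sqrt(sum(res$gaze^2)), 1, tolerance = 1e-12)
  th <- atan(100 / 650) * 180 / pi
  res <- point_of_gaze(c(0, 0, 650), th, 0, calib0)
  expect_equal(res$pog, c(100, 0), tolerance = 1e-9)
  # negating the pan angle negates x and leaves y
  res_neg <- point_of_gaze(c(0, 0, 650), -th, 0, calib0)
  expect_equal(res_neg$pog, c(-100, 0), tolerance = 1e-9)
  expect_error(point_of_gaze(c(0, 0, 650), 90, 0, calib0),
               class = "stereogaze_invalid_sample")
})

test_that("the K-gain correction is the identity at K_actual = K", {
  C <- c(20, -10, 650)
  calib0 <- structure(list(alpha = 1, beta = -0.5, K = 4.2),
                      class = "gaze_calibration")
  res <- point_of_gaze(C, 3, 2, calib0)
  cr <- correct_pog(C, res$pog, K = 4.2, K_actual_filtered = 4.2)
  expect_equal(cr$pog_corrected, res$pog, tolerance = 1e-12)
  expect_equal(cr$theta_corr, 3 + calib0$alpha, tolerance = 1e-9)
  expect_equal(cr$phi_corr, 2 + calib0$beta, tolerance = 1e-9)
})

test_that("the K-gain correction rescales the full gaze-point vector", {
  # direct evaluation: gain on C + lambda g, corrected angles from the
  # corrected gaze point and the unscaled C
  C <- c(0, 0, 650)
  calib0 <- structure(list(alpha = 0, beta = 0, K = 4.2),
                      class = "gaze_calibration")
  res <- point_of_gaze(C, atan(100 / 650) * 180 / pi, 0, calib0)
  cr <- correct_pog(C, res$pog, K = 4.2, K_actual_filtered = 4.2 * 1.1)
  expect_equal(cr$pog_corrected, res$pog / 1.1, tolerance = 1e-9)
  g_expect <- c(res$pog / 1.1, 0) - C
  g_expect <- g_expect / sqrt(sum(g_expect^2))
  expect_equal(cr$theta_corr, atan2(g_expect[1], -g_expect[3]) * 180 / pi)
  expect_equal(cr$phi_corr, asin(g_expect[2]) * 180 / pi)
  expect_error(correct_pog(C, res$pog, 4.2, -1),
               class = "stereogaze_invalid_sample")
})

test_that("the median filter matches a brute-force windowed median", {
  expect_equal(median_filter_track(rep(3, 50)), rep(3, 50))
  x <- rep(1, 60); x[30] <- 100
  expect_equal(median_filter_track(x, 20), rep(1, 60))
  # step edge preserved within half a window
  x <- c(rep(0, 50), rep(1, 50))
  y <- median_filter_track(x, 20)
  expect_equal(length(y), 100)
  edge <- which(diff(y > 0.5) != 0)
  expect_lt(abs(edge - 50), 10)
  # brute force comparison, odd and even widths
  set.seed(51)
  x <- stats::rnorm(80)
  for (w in c(1, 5, 20)) {
    brute <- vapply(seq_along(x), function(i) {
      lo <- max(1, i - floor(w / 2)); hi <- min(length(x), i + ceiling(w / 2) - 1)
      stats::median(x[lo:hi])
    }, numeric(1))
    expect_equal(median_filter_track(x, w), brute)
  }
  expect_equal(median_filter_track(numeric(0)), numeric(0))
})

test_that("one-point calibration recovers the scripted eye parameters", {
  calib <- test_calibration()
  eye <- test_eye()
  # systematic floor set by the convex-mirror aberration of the c estimate
  expect_lt(abs(calib$alpha - eye$alpha_true), 0.1)
  expect_lt(abs(calib$beta - eye$beta_true), 0.1)
  expect_lt(abs(calib$K - eye$K_true), 0.03)
  expect_gte(calib$n_samples_used, 20)
})

test_that("an eye with no axis offset calibrates to zero offsets", {
  geo <- test_rig()
  eye <- eye_params(alpha_true = 0, beta_true = 0)
  sim <- simulate_fixation(c(0, 0), geo, eye, duration_s = 0.3, seed = 13)
  raw <- reconstruct_raw(sim$frames_cam1, sim$frames_cam2, geo)
  calib <- calibrate_one_point(raw, c(0, 0), geo)
  expect_lt(abs(calib$alpha), 0.1)
  expect_lt(abs(calib$beta), 0.1)
})

test_that("calibration refuses too few valid samples", {
  geo <- test_rig()
  raw <- data.frame(timestamp_s = 1:5, cx = 0, cy = 0, cz = 0,
                    pvx = 0, pvy = 0, pvz = -4, K_raw = 4, valid = TRUE)
  expect_error(calibrate_one_point(raw, c(0, 0), geo),
               class = "stereogaze_calibration_error")
})

test_that("noiseless round trips recover true gaze to the method's floor", {
  geo <- test_rig(); eye <- test_eye()
  calib <- test_calibration()
  tg <- target_grid()[c(2, 14, 26, 38, 50), ]
  for (i in seq_len(nrow(tg))) {
    sim <- simulate_fixation(c(tg$x_mm[i], tg$y_mm[i]), geo, eye,
                             duration_s = 0.12, seed = 60 + i)
    g <- reconstruct_gaze(sim$frames_cam1, sim$frames_cam2, geo, calib)
    tr <- sim$truth[match(round(g$timestamp_s, 12),
                          round(sim$truth$timestamp_s, 12)), ]
    use <- g$valid
    expect_gt(sum(use), 20)
    expect_lt(max(abs(g$theta_corr[use] - tr$theta_true[use])), 0.1)
    expect_lt(max(abs(g$phi_corr[use] - tr$phi_true[use])), 0.1)
    expect_lt(max(abs(g$pogc_x_mm[use] - tg$x_mm[i])), 1.5)
    expect_lt(max(abs(g$pogc_y_mm[use] - tg$y_mm[i])), 1.5)
  }
})

test_that("mirror-reflecting the scene negates pan angles and gaze x", {
  geo <- test_rig()
  calib0 <- structure(list(alpha = 0, beta = 0, K = 4.2),
                      class = "gaze_calibration")
  run_one <- function(target_x) {
    eye <- fixate_target(eye_params(alpha_true = 0, beta_true = 0),
                         c(target_x, 40), geo)
    fr <- render_features(eye, geo)
    f1 <- cbind(timestamp_s = seq(0, 0.1, length.out = 25),
                fr[rep(1, 25), -1], row.names = NULL)
    f2 <- cbind(timestamp_s = seq(0.002, 0.1, length.out = 25),
                fr[rep(2, 25), -1], row.names = NULL)
    g <- reconstruct_gaze(f1, f2, geo, calib0)
    g[g$valid, ][1, ]
  }
  a <- run_one(120); b <- run_one(-120)
  expect_equal(a$theta_corr, -b$theta_corr, tolerance = 1e-6)
  expect_equal(a$phi_corr, b$phi_corr, tolerance = 1e-6)
  expect_equal(a$pogc_x_mm, -b$pogc_x_mm, tolerance = 1e-3)
  expect_equal(a$pogc_y_mm, b$pogc_y_mm, tolerance = 1e-3)
})

test_that("all-invalid input produces all-invalid output without crashing", {
  geo <- test_rig()
  f <- data.frame(timestamp_s = seq(0, 0.1, by = 0.01),
                  pupil_x = NA_real_, pupil_y = NA_real_,
                  glint1_x = NA_real_, glint1_y = NA_real_,
                  glint2_x = NA_real_, glint2_y = NA_real_, valid = FALSE)
  g <- reconstruct_gaze(f, f, geo, test_calibration())
  expect_false(any(g$valid))
  expect_equal(nrow(g), 2 * nrow(f))
})

test_that("filtering plus the K constraint never increases POG noise", {
  geo <- test_rig(); eye <- test_eye()
  calib <- test_calibration()
  rms_s2s <- function(x) sqrt(mean(diff(x)^2, na.rm = TRUE))
  for (seed in c(71, 72)) {
    sim <- simulate_fixation(c(60, -40), geo, eye, duration_s = 0.25,
                             pixel_noise_sd = 0.1, seed = seed)
    gf <- reconstruct_gaze(sim$frames_cam1, sim$frames_cam2, geo, calib)
    gr <- reconstruct_gaze(sim$frames_cam1, sim$frames_cam2, geo, calib,
                           filter_width = 1, k_constraint = FALSE)
    expect_lte(rms_s2s(gf$pog_x_mm[gf$valid]), rms_s2s(gr$pog_x_mm[gr$valid]))
    expect_lte(rms_s2s(gf$pog_y_mm[gf$valid]), rms_s2s(gr$pog_y_mm[gr$valid]))
  }
})

test_that("gaze samples report unit gaze vectors and on-screen gaze points", {
  geo <- test_rig(); eye <- test_eye()
  calib <- test_calibration()
  sim <- simulate_fixation(c(-80, 60), geo, eye, duration_s = 0.15,
                           pixel_noise_sd = 0.05, seed = 81)
  g <- reconstruct_gaze(sim$frames_cam1, sim$frames_cam2, geo, calib)
  use <- which(g$valid)
  # POG lies on the screen plane: reconstruct the gaze ray and check Z
  for (i in use[seq(1, length(use), by = 10)]) {
    res <- point_of_gaze(c(g$Cx[i], g$Cy[i], g$Cz[i]), g$theta[i], g$phi[i],
                         calib)
    expect_equal(sqrt(sum(res$gaze^2)), 1, tolerance = 1e-12)
    pog3 <- c(g$Cx[i], g$Cy[i], g$Cz[i]) + res$lambda_g * res$gaze
    expect_lt(abs(pog3[3]), 1e-9)
    expect_equal(res$pog, c(g$pog_x_mm[i], g$pog_y_mm[i]), tolerance = 1e-9)
  }
})
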