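# Forward model checks: the glint solver against the reflection law and a
# brute-force Fermat oracle, Snell-mode pupil imaging, the target grid,
# and the scripted saccade kinematics.

test_that("a co-located camera and illuminator give a retro-reflective glint", {
  geo <- test_rig()
  eye <- fixate_target(test_eye(), c(0, 0), geo)
  px <- glint_pixel(eye, geo$camera1, geo$camera1$nodal_point)
  s_expect <- eye$corneal_center + eye$corneal_radius *
    (geo$camera1$nodal_point - eye$corneal_center) /
    sqrt(sum((geo$camera1$nodal_point - eye$corneal_center)^2))
  expect_equal(as.numeric(px), as.numeric(project_point(geo$camera1, s_expect)),
               tolerance = 1e-9)
})

test_that("glints satisfy the reflection law to solver precision", {
  geo <- test_rig()
  set.seed(99)
  for (i in 1:25) {
    eye <- fixate_target(test_eye(), c(stats::runif(1, -170, 170),
                                       stats::runif(1, -150, 150)), geo)
    eye$corneal_center <- eye$corneal_center +
      c(stats::runif(1, -50, 50), stats::runif(1, -30, 30), stats::runif(1, -20, 20))
    for (cam in list(geo$camera1, geo$camera2)) {
      for (L in list(geo$illuminator1, geo$illuminator2)) {
        px <- glint_pixel(eye, cam, L)
        s <- attr(px, "surface_point")
        expect_lt(reflection_residual(eye, cam, L, s), 1e-9)
      }
    }
  }
})

test_that("the glint solver agrees with a brute-force Fermat search", {
  geo <- test_rig()
  eye <- fixate_target(test_eye(), c(80, -60), geo)
  cam <- geo$camera2; L <- geo$illuminator1
  s <- attr(glint_pixel(eye, cam, L), "surface_point")
  # dense sphere sampling minimizing the optical path length
  set.seed(5)
  U <- matrix(stats::rnorm(3 * 200000), ncol = 3)
  U <- U / sqrt(rowSums(U^2))
  cand <- sweep(U * eye$corneal_radius, 2, eye$corneal_center, "+")
  facing <- rowSums((cand - matrix(eye$corneal_center, nrow(cand), 3, byrow = TRUE)) *
                      (matrix(cam$nodal_point, nrow(cand), 3, byrow = TRUE) - cand)) > 0
  cand <- cand[facing, ]
  f <- sqrt(rowSums(sweep(cand, 2, L, "-")^2)) +
    sqrt(rowSums(sweep(cand, 2, cam$nodal_point, "-")^2))
  k <- which.min(f)
  expect_lt(sqrt(sum((s - cand[k, ])^2)), 0.2) # Monte-Carlo resolution
  f_solver <- sqrt(sum((L - s)^2)) + sqrt(sum((cam$nodal_point - s)^2))
  expect_lte(f_solver, f[k] + 1e-8)
})

test_that("a mirror-symmetric scene produces mirror-symmetric glints", {
  geo <- test_rig()
  # eye on the rig midplane x = 60 looking straight ahead
  eye <- test_eye()
  eye <- orient_eye(eye, eye$alpha_true, eye$beta_true, geo) # optical axis along -z
  p1 <- glint_pixel(eye, geo$camera1, geo$illuminator1)
  p2 <- glint_pixel(eye, geo$camera2, geo$illuminator2)
  # cameras are mirror images of each other: pixel x mirrors about the pp
  expect_equal(p1[1] - geo$camera1$principal_point[1],
               -(p2[1] - geo$camera2$principal_point[1]), tolerance = 1e-6)
  expect_equal(p1[2], p2[2], tolerance = 1e-6)
})

test_that("no-refraction pupil imaging is plain projection", {
  geo <- test_rig()
  eye <- fixate_target(test_eye(), c(50, 30), geo)
  expect_equal(as.numeric(pupil_pixel(eye, geo$camera1, "no_refraction")),
               as.numeric(project_point(geo$camera1, pupil_center(eye))))
})

test_that("snell-mode chief rays obey Snell's law and hit the pupil center", {
  geo <- test_rig()
  set.seed(7)
  for (i in 1:10) {
    eye <- fixate_target(test_eye(), c(stats::runif(1, -150, 150),
                                       stats::runif(1, -120, 120)), geo)
    for (cam in list(geo$camera1, geo$camera2)) {
      px <- pupil_pixel(eye, cam, "snell")
      s <- attr(px, "surface_point")
      n <- (s - eye$corneal_center) / eye$corneal_radius
      di <- (s - cam$nodal_point) / sqrt(sum((s - cam$nodal_point)^2))
      ci <- -sum(di * n)
      eta <- 1 / eye$refractive_index
      dt <- eta * di + (eta * ci - sqrt(1 - eta^2 * (1 - ci^2))) * n
      # refracted ray passes through the true pupil center
      off <- pupil_center(eye) - s
      miss <- sqrt(sum((off - sum(off * dt) * dt)^2))
      expect_lt(miss, 1e-9)
      # Snell's law at the surface
      sin_i <- sqrt(sum((di - sum(di * -n) * -n)^2))
      sin_t <- sqrt(sum((dt - sum(dt * -n) * -n)^2))
      expect_equal(sin_i, eye$refractive_index * sin_t, tolerance = 1e-9)
    }
  }
})

test_that("refraction displaces the apparent pupil mainly in depth", {
  geo <- test_rig()
  eye <- fixate_target(test_eye(), c(0, 0), geo)
  stream <- function(mode) {
    fr <- render_features(eye, geo, mode = mode)
    pair <- synchronize_frames(
      cbind(timestamp_s = 0, fr[fr$cam == 1, -1]),
      cbind(timestamp_s = 0, fr[fr$cam == 2, -1]))
    estimate_virtual_pupil(pair[1, ], geo)
  }
  pv_true <- stream("no_refraction")
  pv_snell <- stream("snell")
  expect_equal(pv_true, pupil_center(eye), tolerance = 1e-6)
  # virtual pupil sits behind the true pupil (larger |depth from cornea|)
  d_true <- sqrt(sum((pv_true - eye$corneal_center)^2))
  d_snell <- sqrt(sum((pv_snell - eye$corneal_center)^2))
  expect_gt(abs(d_snell - d_true), 0.1)
})

test_that("render_features is deterministic per seed and flags off-sensor eyes", {
  geo <- test_rig()
  eye <- fixate_target(test_eye(), c(0, 0), geo)
  a <- render_features(eye, geo, pixel_noise_sd = 0.1, seed = 4)
  b <- render_features(eye, geo, pixel_noise_sd = 0.1, seed = 4)
  expect_identical(a, b)
  c1 <- render_features(eye, geo, pixel_noise_sd = 0.1, seed = 5)
  expect_false(isTRUE(all.equal(a$pupil_x, c1$pupil_x)))
  noiseless1 <- render_features(eye, geo)
  noiseless2 <- render_features(eye, geo)
  expect_identical(noiseless1, noiseless2)
  # eye rotated 90 deg away: no valid features
  away <- eye
  away$optical_axis <- c(1, 0, 0)
  away$corneal_center <- c(60, 180, 5000) # far outside the field of view
  fr <- render_features(away, geo)
  expect_false(any(fr$valid))
})

test_that("the target grid matches the validation-study design", {
  tg <- target_grid()
  expect_equal(nrow(tg), 54)
  expect_equal(sum(tg$ecc_deg == 15), 6)
  first <- tg[tg$ecc_deg == 3 & tg$dir_deg == 0, ]
  expect_equal(first$x_mm, 650 * tan(3 * pi / 180), tolerance = 1e-12)
  expect_equal(first$y_mm, 0)
  # 12-direction rings are symmetric under 180-degree rotation
  for (e in c(3, 6, 9, 12)) {
    ring <- tg[tg$ecc_deg == e, ]
    rot <- cbind(-ring$x_mm, -ring$y_mm)
    for (i in seq_len(nrow(ring))) {
      d <- sqrt((ring$x_mm - rot[i, 1])^2 + (ring$y_mm - rot[i, 2])^2)
      expect_lt(min(d), 1e-9)
    }
  }
})

test_that("scripted saccades follow the main-sequence raised-cosine profile", {
  geo <- test_rig(); eye <- test_eye()
  # zero-amplitude saccade: constant orientation
  sc0 <- trial_script(c(0, 0), fixation_xy_mm = c(0, 0), duration_s = 0.2, seed = 2)
  tr0 <- simulate_trial(sc0, geo, eye)
  expect_equal(diff(range(tr0$truth$theta_true)), 0)
  expect_equal(diff(range(tr0$truth$phi_true)), 0)
  # 10-deg saccade: true peak velocity = v0 (1 - exp(-10/5)) within 1%
  tgt <- c(650 * tan(10 * pi / 180), 0)
  sc <- trial_script(tgt, fixation_xy_mm = c(0, 0), target_onset_s = 0.2,
                     duration_s = 0.6, v0 = 500, Amp0 = 5, seed = 3)
  tr <- simulate_trial(sc, geo, eye)
  tt <- tr$truth
  v <- sqrt(diff(tt$theta_true)^2 + diff(tt$phi_true)^2) / diff(tt$timestamp_s)
  amp <- sqrt(diff(range(tt$theta_true))^2 + diff(range(tt$phi_true))^2)
  v_expect <- 500 * (1 - exp(-amp / 5))
  expect_equal(max(v), v_expect, tolerance = 0.01)
  # the two cameras' timestamp sets are disjoint under jitter
  expect_length(intersect(tr$frames_cam1$timestamp_s, tr$frames_cam2$timestamp_s), 0)
  # targets outside the screen are rejected
  expect_error(simulate_trial(trial_script(c(5000, 0)), geo, eye),
               class = "stereogaze_invalid_input")
})

test_that("measured corneal-pupil distance is near-constant without refraction", {
  geo <- test_rig(); eye0 <- test_eye()
  tg <- target_grid()[c(1, 10, 20, 30, 40, 50), ]
  K <- vapply(seq_len(nrow(tg)), function(i) {
    eye <- fixate_target(eye0, c(tg$x_mm[i], tg$y_mm[i]), geo)
    fr <- render_features(eye, geo)
    pair <- synchronize_frames(
      cbind(timestamp_s = 0, fr[fr$cam == 1, -1]),
      cbind(timestamp_s = 0, fr[fr$cam == 2, -1]))
    pv <- estimate_virtual_pupil(pair[1, ], geo)
    cc <- estimate_corneal_center(pair[1, ], geo)
    sqrt(sum((cc$c - pv)^2))
  }, numeric(1))
  # constant up to the convex-mirror aberration of the corneal-center step
  expect_lt(max(abs(K - eye0$K_true)), 0.05)
  expect_lt(diff(range(K)), 0.02)
})

test_that("snell-mode K varies systematically over the grid", {
  geo <- test_rig(); eye0 <- test_eye()
  tg <- target_grid()[c(1, 13, 25, 37, 49, 52), ]
  K <- vapply(seq_len(nrow(tg)), function(i) {
    eye <- fixate_target(eye0, c(tg$x_mm[i], tg$y_mm[i]), geo)
    fr <- render_features(eye, geo, mode = "snell")
    pair <- synchronize_frames(
      cbind(timestamp_s = 0, fr[fr$cam == 1, -1]),
      cbind(timestamp_s = 0, fr[fr$cam == 2, -1]))
    pv <- estimate_virtual_pupil(pair[1, ], geo)
    cc <- estimate_corneal_center(pair[1, ], geo)
    sqrt(sum((cc$c - pv)^2))
  }, numeric(1))
  expect_gt(diff(range(K)), 0.01)
  expect_gt(mean(K), eye0$K_true) # virtual pupil sits deeper than the real one
})
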