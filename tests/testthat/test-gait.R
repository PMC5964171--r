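# Gait processing: filtering, marker-to-angle conversion, stride assembly,
# pooling, worked-example scalars.

test_that("zero-phase Butterworth filter meets its response contract", {
  # DC gain exactly 1
  expect_equal(lowpass_filter(rep(3.7, 300), fs = 250, cutoff = 20),
               rep(3.7, 300), tolerance = 1e-9)
  # 100 Hz sinusoid at fs 1000, cutoff 20: attenuated below 1% (the squared
  # 4th-order magnitude response at 5x cutoff is ~(1/625)^2)
  t <- seq(0, 1, by = 1e-3)
  y <- lowpass_filter(sin(2 * pi * 100 * t), fs = 1000, cutoff = 20)
  expect_lt(max(abs(y[100:900])), 0.01)
  # white noise: variance contracts
  set.seed(2)
  x <- stats::rnorm(2000)
  expect_lt(stats::var(lowpass_filter(x, fs = 1000, cutoff = 20)),
            stats::var(x))
  # passband is preserved
  yl <- lowpass_filter(sin(2 * pi * 2 * t), fs = 1000, cutoff = 20)
  expect_equal(max(abs(yl[200:800])), 1, tolerance = 0.01)
  expect_mousegait_error(lowpass_filter(x, fs = 30, cutoff = 20),
                         "mousegait_input_error")
})

test_that("marker-to-angle conversion inverts forward kinematics", {
  m <- test_model()
  p <- gait_params()
  ang <- generate_angles(p)
  mk <- markers_from_angles(m, ang)
  trial <- marker_trial(ang$time, mk, p$frame_rate)
  back <- joint_angles_from_markers(trial)
  for (cc in c("pelvic_tilt", "hip_flexion", "knee_extension",
               "ankle_flexion"))
    expect_equal(back[[cc]], ang[[cc]], tolerance = 1e-9)
})

test_that("angle conversion geometry cases", {
  m <- test_model()
  # collinear hip-knee-ankle: knee gencoord 0 (fully extended); right angle
  # at the knee: 90 degrees from extension
  base <- data.frame(pelvic_tilt = c(0, 0), hip_flexion = c(0.4, 0.4),
                     knee_extension = c(0, -pi / 2),
                     ankle_flexion = c(0, 0))
  base$time <- c(0, 0.01)
  mk <- markers_from_angles(m, base)
  trial <- marker_trial(base$time, mk, 100)
  ang <- joint_angles_from_markers(trial)
  expect_equal(ang$knee_extension[1], 0, tolerance = 1e-12)
  expect_equal(abs(ang$knee_extension[2]), pi / 2, tolerance = 1e-12)
  # coincident markers -> degenerate frame
  mk$knee <- mk$hip
  expect_mousegait_error(
    joint_angles_from_markers(marker_trial(base$time, mk, 100)),
    "mousegait_degenerate_frame")
})

test_that("duty factor and body-weight normalization worked examples", {
  # printed stride: duration 0.128 s, transition at 0.072 s
  s <- stride_record(seq(0, 1, length.out = 11),
                     data.frame(hip_flexion = rep(0.5, 11)),
                     data.frame(f_craniocaudal = c(rep(0, 6), rep(1e-3, 5)),
                                f_vertical = c(rep(0, 6), rep(0.1, 5))),
                     transition = 0.072 / 0.128, duration = 0.128)
  expect_equal(duty_factor(s), 0.4375)
  expect_equal(round(duty_factor(s), 2), 0.44)
  s2 <- s; s2$transition <- 0.5
  expect_equal(duty_factor(s2), 0.5)
  # percent body weight with the printed subject mass
  expect_equal(grf_percent_bodyweight(0.02, 0.0187, 9.8), 10.9,
               tolerance = 0.005)
  expect_equal(grf_percent_bodyweight(0.015, 0.0187, 9.8), 8.19,
               tolerance = 0.005)
  expect_equal(grf_percent_bodyweight(0, 0.0187), 0)
})

test_that("stride pooling: means, CIs and spline exactness", {
  m <- test_model()
  set <- generate_trial_set(gait_params(seed = 3), n_trials = 5,
                            amp_cv = 0, duration_cv = 0, model = m)
  strides <- lapply(set, `[[`, "stride")
  pool <- normalize_and_pool(strides, 61)
  # identical strides: zero CI, mean = the stride
  expect_equal(max(abs(as.matrix(pool$ci95))), 0)
  expect_equal(pool$n_trials, 5)
  # two strides offset by a constant: mean halfway, ci95 = 1.96 (c/2)/sqrt(2)
  s1 <- strides[[1]]
  s2 <- s1; s2$joint_angles$hip_flexion <- s1$joint_angles$hip_flexion + 0.1
  pool2 <- normalize_and_pool(list(s1, s2), 31)
  expect_equal(pool2$mean$hip_flexion,
               stats::spline(s1$normalized_time,
                             s1$joint_angles$hip_flexion + 0.05,
                             xout = pool2$normalized_time,
                             method = "fmm")$y,
               tolerance = 1e-9)
  # two points at x and x + c: sd = c/sqrt(2), SE = sd/sqrt(2) = c/2,
  # so ci95 = 1.96 c/2 pointwise
  expect_equal(unique(round(pool2$ci95$hip_flexion, 12)),
               round(1.96 * 0.1 / 2, 12))
  # permutation invariance
  pool3 <- normalize_and_pool(list(s2, s1), 31)
  expect_equal(pool3$mean, pool2$mean)
  expect_equal(pool3$ci95, pool2$ci95)
  # cubic resampling is exact for cubic polynomials
  tt <- seq(0, 1, length.out = 41)
  cub <- 1 + tt - 2 * tt^2 + 0.5 * tt^3
  sc <- s1
  sc$normalized_time <- tt
  sc$joint_angles <- data.frame(hip_flexion = cub)
  sc$grf <- data.frame(f_craniocaudal = rep(0, 41), f_vertical = rep(0, 41))
  sc$grf$f_vertical[tt >= sc$transition] <- 0.1
  poolc <- normalize_and_pool(list(sc), 101)
  grid <- poolc$normalized_time
  expect_equal(poolc$mean$hip_flexion,
               1 + grid - 2 * grid^2 + 0.5 * grid^3, tolerance = 1e-10)
  expect_mousegait_error(normalize_and_pool(strides, 3),
                         "mousegait_input_error")
})

test_that("process_trial assembles a consistent stride from raw trials", {
  m <- test_model()
  p <- gait_params(marker_noise_sd = 0)
  tr <- generate_trial(p, m)
  st <- process_trial(tr$markers, tr$forces)
  expect_s3_class(st, "stride_record")
  expect_equal(st$transition, 1 - p$duty_factor, tolerance = 1e-9)
  expect_equal(st$duration, p$stride_duration)
  expect_equal(st$speed, p$speed, tolerance = 0.02)
  # swing GRF identically zero by construction
  expect_true(all(st$grf$f_vertical[st$normalized_time <
                                      st$transition - 1e-9] == 0))
  # filtered noise-free angles track the generating angles closely
  rmse <- kinematic_rmse(st$normalized_time, st$joint_angles,
                         tr$stride$normalized_time,
                         tr$stride$joint_angles[, names(st$joint_angles)])
  expect_true(all(rmse < 1.5))
})

test_that("marker noise round trip stays within the filtered-angle bound", {
  m <- test_model()
  p <- gait_params(marker_noise_sd = 5e-4, seed = 9)
  tr <- generate_trial(p, m)
  st <- process_trial(tr$markers, tr$forces)
  rmse <- kinematic_rmse(st$normalized_time, st$joint_angles,
                         tr$stride$normalized_time,
                         tr$stride$joint_angles[, names(st$joint_angles)])
  expect_true(all(rmse < 5))   # degrees, at 0.5 mm digitization noise
})

test_that("stride record validates its invariants", {
  nt <- seq(0, 1, length.out = 5)
  ja <- data.frame(hip_flexion = rep(0, 5))
  grf0 <- data.frame(f_craniocaudal = rep(0, 5), f_vertical = rep(0, 5))
  expect_mousegait_error(
    stride_record(nt, ja, grf0, transition = 0, duration = 0.1),
    "mousegait_input_error")
  grf_bad <- grf0; grf_bad$f_vertical[1] <- 1
  expect_mousegait_error(
    stride_record(nt, ja, grf_bad, transition = 0.5, duration = 0.1),
    "mousegait_input_error")
})
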