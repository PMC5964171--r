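# Static optimization: QP kernel oracles, closed-form toys, parameter
# recovery, diagnostics.

test_that("box QP equals grid search and a general-purpose optimizer", {
  set.seed(21)
  for (rep in 1:4) {
    B <- matrix(stats::rnorm(9), 3, 3)
    H <- crossprod(B) + diag(3) * 0.5
    g <- stats::rnorm(3)
    sol <- solve_box_qp(H, g, 0, 1)
    expect_true(sol$converged)
    # grid-search oracle
    gr <- seq(0, 1, length.out = 41)
    grid <- as.matrix(expand.grid(gr, gr, gr))
    vals <- 0.5 * rowSums((grid %*% H) * grid) + grid %*% g
    best <- grid[which.min(vals), ]
    expect_lt(max(abs(sol$x - best)), 0.05)  # within grid resolution
    # L-BFGS-B oracle (independent solver)
    o <- stats::optim(rep(0.5, 3),
                      function(x) 0.5 * sum(x * (H %*% x)) + sum(g * x),
                      function(x) drop(H %*% x) + g,
                      method = "L-BFGS-B", lower = 0, upper = 1,
                      control = list(factr = 1e2))
    expect_lt(max(abs(sol$x - o$par)), 1e-5)
  }
})

test_that("single-muscle inversion: a = tau/(Fbar r); zero demand is idle", {
  m <- reduced_model()
  m$mtus <- m$mtus["RF"]
  cv <- test_curves()
  acts <- actuator_set(m, reserve_weight = 1e6)
  q <- mousegait:::calibration_pose(m)
  qd <- stats::setNames(rep(0, 5), names(q))
  r <- moment_arm(m, q, "RF", "knee_extension")
  Fbar <- mtu_force(m$mtus$RF$params, cv, 1, mtu_length(m, q, "RF"), 0)
  for (frac in c(0.25, 0.6, 0.9)) {
    s <- solve_timestep(m, q, qd, c(knee_extension = frac * Fbar * r),
                        acts, cv)
    expect_equal(s$activations[["RF"]], frac, tolerance = 1e-4)
  }
  s0 <- solve_timestep(m, q, qd, c(knee_extension = 0), acts, cv)
  expect_lt(max(abs(s0$activations)), 1e-8)
  expect_lt(max(abs(s0$reserves)), 1e-10)
})

test_that("two identical muscles share the demand equally (Lagrangian)", {
  m <- test_model()
  m$mtus <- m$mtus["RF"]
  m$mtus$RF2 <- m$mtus$RF
  cv <- test_curves()
  acts <- actuator_set(m, reserve_weight = 1e6)
  q <- mousegait:::calibration_pose(m)
  qd <- stats::setNames(rep(0, 5), names(q))
  r <- moment_arm(m, q, "RF", "knee_extension")
  Fbar <- mtu_force(m$mtus$RF$params, cv, 1, mtu_length(m, q, "RF"), 0)
  tau <- 0.5 * Fbar * r
  s <- solve_timestep(m, q, qd, c(knee_extension = tau), acts, cv)
  expect_equal(s$activations[["RF"]], 0.25, tolerance = 1e-4)
  expect_equal(s$activations[["RF2"]], 0.25, tolerance = 1e-4)
  # grid-search oracle on the 2-muscle toy with reserve remainder cost
  a_grid <- seq(0, 1, length.out = 201)
  W <- 1e6 / acts$reserve_optimal_moment[["knee_extension"]]^2
  obj <- outer(a_grid, a_grid, function(a1, a2)
    a1^2 + a2^2 + W * (tau - (a1 + a2) * Fbar * r)^2)
  best <- which(obj == min(obj), arr.ind = TRUE)[1, ]
  expect_equal(unname(s$activations), c(a_grid[best[1]], a_grid[best[2]]),
               tolerance = 0.01)
})

test_that("demand beyond muscle capacity saturates and recruits the reserve", {
  m <- test_model()
  cv <- test_curves()
  acts <- actuator_set(m, reserve_weight = 1e6)
  q <- mousegait:::calibration_pose(m)
  qd <- stats::setNames(rep(0, 5), names(q))
  gains <- mousegait:::timestep_gains(m, q, qd, acts, cv)
  gk <- gains$G["knee_extension", ]
  cap <- sum(gk[gk > 0])
  s <- solve_timestep(m, q, qd, c(knee_extension = 1.2 * cap), acts, cv)
  ext <- names(which(gk > 1e-6))
  expect_true(all(s$activations[ext] > 0.999))
  expect_equal(s$reserves[["knee_extension"]], 0.2 * cap, tolerance = 1e-6)
})

test_that("moment balance holds exactly at every accepted timestep", {
  m <- test_model()
  cv <- test_curves()
  acts <- actuator_set(m)
  q <- test_pose()
  qd <- stats::setNames(c(0, 2, 0, -3, 1), names(q))
  tau <- c(pelvic_tilt = 0.02, hip_flexion = -0.002,
           hip_adduction = 5e-4, knee_extension = 0.001,
           ankle_flexion = -0.0015)
  s <- solve_timestep(m, q, qd, tau, acts, cv)
  gains <- mousegait:::timestep_gains(m, q, qd, acts, cv)
  A <- cbind(gains$G, t(gains$Jres))
  recon <- drop(A %*% c(s$activations, s$residuals)) + s$reserves
  expect_equal(unname(recon), unname(tau[gains$coords]), tolerance = 1e-12)
  expect_true(all(s$activations >= 0 & s$activations <= 1))
})

test_that("objective is non-increasing as muscle capacity grows", {
  m <- reduced_model()
  cv <- test_curves()
  q <- mousegait:::calibration_pose(m)
  qd <- stats::setNames(rep(0, 5), names(q))
  tau <- c(knee_extension = 0.001, hip_flexion = -0.001,
           ankle_flexion = 5e-4)
  objs <- vapply(c(1, 1.5, 2.5), function(scale) {
    ms <- m
    for (a in names(ms$mtus)) ms$mtus[[a]]$params$f_max <-
        ms$mtus[[a]]$params$f_max * scale
    solve_timestep(ms, q, qd, tau, actuator_set(ms), cv)$objective
  }, numeric(1))
  expect_true(all(diff(objs) <= 1e-10))
})

test_that("stride solve recovers imposed activations where unique", {
  m <- reduced_model()
  cv <- test_curves()
  acts <- actuator_set(m, reserve_weight = 1e6)
  p <- gait_params()
  tr <- generate_trial(p, m, n = 41)
  stride <- tr$stride
  time <- stride$normalized_time * stride$duration
  ph <- stride$normalized_time
  imposed <- cbind(SM = 0.4 + 0.2 * sin(2 * pi * ph),
                   RF = 0.5 + 0.3 * cos(2 * pi * ph),
                   LG = 0.3 + 0.1 * sin(4 * pi * ph))
  dt <- time[2] - time[1]
  qmat <- stride$joint_angles
  qd_m <- vapply(names(qmat),
                 function(cc) mousegait:::series_deriv(qmat[[cc]], dt),
                 numeric(length(time)))
  tau_mat <- matrix(0, length(time), 5,
                    dimnames = list(NULL, acts$coordinates))
  for (i in seq_along(time)) {
    qi <- stats::setNames(as.numeric(qmat[i, ]), names(qmat))
    gi <- mousegait:::timestep_gains(
      m, qi, stats::setNames(qd_m[i, ], names(qmat)), acts, cv)
    tau_mat[i, ] <- gi$G %*% imposed[i, ]
  }
  suppressWarnings(
    sol <- solve_stride(m, stride,
                        data.frame(time = time, tau_mat,
                                   check.names = FALSE), acts, cv))
  expect_lt(max(abs(sol$activations - imposed)), 1e-3)
  expect_true(all(sol$kkt < 1e-4 * max(abs(tau_mat)) + 1e-8))
})

test_that("timesteps are independent: stride solve equals per-step solves", {
  m <- reduced_model()
  cv <- test_curves()
  acts <- actuator_set(m)
  p <- gait_params()
  tr <- generate_trial(p, m, n = 21)
  stride <- tr$stride
  time <- stride$normalized_time * stride$duration
  n <- length(time)
  mom <- data.frame(time = time,
                    hip_flexion = 1e-3 * sin(2 * pi * stride$normalized_time),
                    knee_extension = 5e-4 * cos(2 * pi * stride$normalized_time))
  suppressWarnings(sol <- solve_stride(m, stride, mom, acts, cv))
  dt <- time[2] - time[1]
  qmat <- stride$joint_angles
  for (i in c(3, 11, 19)) {
    qi <- stats::setNames(as.numeric(qmat[i, ]), names(qmat))
    qdi <- stats::setNames(
      vapply(names(qmat),
             function(cc) mousegait:::series_deriv(qmat[[cc]], dt)[i],
             numeric(1)), names(qmat))
    s <- solve_timestep(m, qi, qdi,
                        c(hip_flexion = mom$hip_flexion[i],
                          knee_extension = mom$knee_extension[i]), acts, cv)
    expect_equal(unname(sol$activations[i, ]), unname(s$activations),
                 tolerance = 1e-10)
  }
})

test_that("diagnostics: idle reserves unflagged, muscle-free coordinate
           fully reserve-borne", {
  m <- test_model()
  cv <- test_curves()
  acts <- actuator_set(m)
  p <- gait_params()
  tr <- generate_trial(p, m, n = 31)
  stride <- tr$stride
  time <- stride$normalized_time * stride$duration
  # pelvic-tilt-only demand: no muscle spans it, reserve takes all of it
  mom <- data.frame(time = time,
                    pelvic_tilt = 0.01 * (1 + sin(2 * pi * time / 0.128)))
  suppressWarnings(sol <- solve_stride(m, stride, mom, acts, cv))
  diag <- actuator_diagnostics(sol, mom, stride$grf)
  share <- diag$reserve_share$pelvic_tilt
  expect_equal(share[abs(mom$pelvic_tilt) > 1e-3],
               rep(1, sum(abs(mom$pelvic_tilt) > 1e-3)), tolerance = 1e-3)
  expect_true(diag$flags[["pelvic_tilt"]])
  # zero-reserve solution flags nothing
  sol0 <- sol
  sol0$reserves[] <- 0
  d0 <- actuator_diagnostics(sol0, mom, stride$grf)
  expect_false(any(d0$flags))
  expect_true(all(as.matrix(d0$reserve_share) == 0))
})
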