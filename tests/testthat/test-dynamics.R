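# Rigid-body dynamics: inverse-dynamics oracles, coordinate limit forces,
# the RK45 integrator, and the FD-ID consistency property.

test_that("static pose, no GRF: moments equal the gravitational statics", {
  m <- test_model()
  q <- test_pose()[mousegait:::sagittal_coords]
  n <- 101
  time <- seq(0, 0.1, length.out = n)
  qmat <- as.data.frame(lapply(q, rep, n))
  tau <- inverse_dynamics(m, time, qmat)
  # independent statics oracle: holding the pose needs the gravity moment,
  # tau_j = sum_k m_k g (dy_k/dq_j), from the chain Jacobians
  bodies <- mousegait:::planar_bodies(m)
  fk <- mousegait:::fk_planar(m, q, bodies = bodies)
  oracle <- vapply(1:4, function(j)
    sum(vapply(1:4, function(k)
      bodies$mass[k] * m$gravity * fk$Jcom[[k]][2, j], numeric(1))),
    numeric(1))
  expect_equal(unlist(tau[51, mousegait:::sagittal_coords],
                      use.names = FALSE), oracle, tolerance = 1e-10)
})

test_that("single-segment pendulum matches the closed form to < 0.1% RMS", {
  m <- pendulum_model()
  A <- 0.3; w <- 2 * pi * 8
  n <- 1001
  time <- seq(0, 0.25, length.out = n)
  qh <- A * sin(w * time)
  qmat <- data.frame(pelvic_tilt = 0, hip_flexion = qh,
                     knee_extension = 0, ankle_flexion = 0)
  tau <- inverse_dynamics(m, time, qmat)
  th <- m$segments[m$segments$name == "thigh", ]
  Io <- th$izz + th$mass * (th$chain_x^2 + th$chain_y^2)
  phi2 <- qh - pi / 2
  dydq <- cos(phi2) * th$chain_x - sin(phi2) * th$chain_y
  oracle <- Io * (-A * w^2 * sin(w * time)) + th$mass * m$gravity * dydq
  rel <- sqrt(mean((tau$hip_flexion - oracle)^2)) / sqrt(mean(oracle^2))
  expect_lt(rel, 1e-3)
})

test_that("massless limb under pure vertical GRF gives lever moments", {
  m <- massless_model()
  q <- test_pose()[mousegait:::sagittal_coords]
  n <- 101
  time <- seq(0, 0.1, length.out = n)
  qmat <- as.data.frame(lapply(q, rep, n))
  F <- 0.21
  grf <- data.frame(f_craniocaudal = rep(0, n), f_vertical = rep(F, n))
  tau <- inverse_dynamics(m, time, qmat, grf)
  fk <- mousegait:::fk_planar(m, q)
  oracle <- -drop(t(fk$J_cop) %*% c(0, F))
  expect_equal(unlist(tau[51, mousegait:::sagittal_coords],
                      use.names = FALSE), oracle, tolerance = 1e-12)
  # linearity in the applied GRF (superposition)
  tau2 <- inverse_dynamics(m, time, qmat,
                           data.frame(f_craniocaudal = rep(0, n),
                                      f_vertical = rep(2 * F, n)))
  expect_equal(tau2$ankle_flexion, 2 * tau$ankle_flexion, tolerance = 1e-12)
})

test_that("CoP sensitivity: zero offset is the identity, offsets are
           antisymmetric on a massless limb", {
  m <- massless_model()
  q <- test_pose()[mousegait:::sagittal_coords]
  n <- 61
  time <- seq(0, 0.1, length.out = n)
  qmat <- as.data.frame(lapply(q, rep, n))
  grf <- data.frame(f_craniocaudal = rep(0, n), f_vertical = rep(0.2, n))
  suppressWarnings(
    cs <- cop_sensitivity(m, time, qmat, grf, offsets = c(-0.002, 0.002)))
  d <- cs$deltas
  zero_row <- d[d$offset == 0, ]
  expect_true(all(abs(unlist(zero_row[-1])) < 1e-15))
  # constant vertical force: moment delta = -dF per coordinate distal of
  # the CoP lever; equal and opposite offsets give equal and opposite deltas
  up <- unlist(d[d$offset == 0.002, -1])
  dn <- unlist(d[d$offset == -0.002, -1])
  expect_equal(up[c("hip_flexion", "knee_extension", "ankle_flexion")],
               -dn[c("hip_flexion", "knee_extension", "ankle_flexion")],
               tolerance = 1e-9)
  # the lever change is bounded by |offset| * F and is non-trivial
  expect_gt(abs(up[["ankle_flexion"]]), 0)
  expect_lte(abs(up[["ankle_flexion"]]), 0.002 * 0.2 + 1e-12)
})

test_that("coordinate limit force: dead zone, linear spring, dissipation", {
  clf <- list(lower = -1, upper = 1, stiffness = 0.5, damping = 0.01,
              transition_width = mousegait:::deg2rad(2))
  # strictly inside: zero for any velocity
  expect_equal(limit_moment(clf, 0, 0), 0)
  expect_equal(limit_moment(clf, 0.5, 50), 0)
  # beyond the limit: restoring linear spring (q = upper + 0.1 -> -0.1 k)
  expect_equal(limit_moment(clf, 1.1, 0), -0.1 * 0.5, tolerance = 1e-12)
  expect_equal(limit_moment(clf, -1.1, 0), 0.1 * 0.5, tolerance = 1e-12)
  # damping dissipates energy over any closed trajectory
  t <- seq(0, 2 * pi, length.out = 2001)
  q <- 1.05 + 0.1 * sin(t)          # oscillating beyond the upper limit
  qd <- 0.1 * cos(t)
  total <- vapply(seq_along(t), function(i) limit_moment(clf, q[i], qd[i]),
                  numeric(1))
  spring <- vapply(seq_along(t), function(i) limit_moment(
    list(lower = -1, upper = 1, stiffness = 0.5, damping = 0,
         transition_width = clf$transition_width), q[i], qd[i]), numeric(1))
  damp_power <- -(total - spring) * qd   # power extracted by damping
  expect_gt(sum(damp_power) * (t[2] - t[1]), 0)
})

test_that("RK45 integrator reproduces closed-form solutions", {
  # linear decay
  sol <- ode_rk45(function(t, y) -3 * y, c(0, 2), 1,
                  times = seq(0, 2, 0.1), rtol = 1e-8, atol = 1e-12)
  expect_lt(max(abs(sol$y[, 1] - exp(-3 * sol$time))), 1e-6)
  # harmonic oscillator preserves both components
  sol2 <- ode_rk45(function(t, y) c(y[2], -y[1]), c(0, 10), c(1, 0),
                   times = seq(0, 10, 0.25), rtol = 1e-8, atol = 1e-12)
  expect_lt(max(abs(sol2$y[, 1] - cos(sol2$time))), 1e-5)
})

test_that("torque-driven pendulum matches a high-precision reference", {
  m <- pendulum_model()
  # constant small torque about the hip from a flexed start
  tau_fun <- function(t) c(0, 2e-5, 0, 0)
  q0 <- c(pelvic_tilt = 0, hip_flexion = 0.5, knee_extension = 0,
          ankle_flexion = 0)
  qd0 <- q0 * 0
  fwd <- forward_dynamics_torque(m, tau_fun, q0, qd0, c(0, 0.1),
                                 times = seq(0, 0.1, 0.005), rtol = 1e-8,
                                 locked = c("pelvic_tilt", "knee_extension",
                                            "ankle_flexion"))
  # independent reference: 1-DoF ODE integrated by fine fixed-step RK4
  th <- m$segments[m$segments$name == "thigh", ]
  Io <- th$izz + th$mass * (th$chain_x^2 + th$chain_y^2)
  acc <- function(q, qd) {
    phi2 <- q - pi / 2
    dydq <- cos(phi2) * th$chain_x - sin(phi2) * th$chain_y
    (2e-5 - th$mass * m$gravity * dydq) / Io
  }
  h <- 1e-5; y <- c(0.5, 0)
  ref <- numeric(0)
  nsteps <- round(0.1 / h)
  f <- function(s) c(s[2], acc(s[1], s[2]))
  for (i in 0:nsteps) {
    if (i %% 500 == 0) ref <- c(ref, y[1])   # every 0.005 s
    k1 <- f(y); k2 <- f(y + h / 2 * k1); k3 <- f(y + h / 2 * k2)
    k4 <- f(y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  expect_equal(length(ref), nrow(fwd$q))
  expect_lt(max(abs(fwd$q[, "hip_flexion"] - ref)), 1e-4)
})

test_that("zero torque, no gravity, limits inactive: state is constant", {
  m <- test_model()
  m$gravity <- 0
  q0 <- test_pose()[mousegait:::sagittal_coords]
  fwd <- forward_dynamics_torque(m, function(t) rep(0, 4), q0, q0 * 0,
                                 c(0, 0.05), times = seq(0, 0.05, 0.01))
  expect_equal(max(abs(sweep(fwd$q, 2, q0))), 0, tolerance = 1e-9)
  expect_equal(max(abs(fwd$qd)), 0, tolerance = 1e-9)
})

test_that("passive unforced chain conserves mechanical energy", {
  m <- test_model()
  q0 <- c(pelvic_tilt = 0.1, hip_flexion = 0.4, knee_extension = -0.3,
          ankle_flexion = 0.1)
  fwd <- forward_dynamics_torque(m, function(t) rep(0, 4), q0, q0 * 0,
                                 c(0, 0.05), times = seq(0, 0.05, 0.002),
                                 rtol = 1e-8)
  bodies <- mousegait:::planar_bodies(m)
  energy <- vapply(seq_along(fwd$time), function(i) {
    q <- fwd$q[i, ]; qd <- fwd$qd[i, ]
    M <- mousegait:::chain_mass_matrix(m, q, bodies)
    fk <- mousegait:::fk_planar(m, q, bodies = bodies)
    ke <- 0.5 * drop(t(qd) %*% M %*% qd)
    pe <- sum(bodies$mass * m$gravity * fk$coms[2, ])
    ke + pe
  }, numeric(1))
  scale <- max(abs(energy - energy[1]), 0) + abs(max(energy) - min(energy))
  expect_lt(max(abs(energy - energy[1])),
            1e-5 * max(abs(energy[1]), 1e-9) + 1e-12)
})

test_that("FD-ID round trip reproduces the kinematics to < 1 degree RMS", {
  m <- test_model()
  p <- gait_params()
  ang <- generate_angles(p, n = 801)
  grf <- generate_grf(p, n = 801)
  time <- ang$time
  qmat <- ang[, mousegait:::sagittal_coords]
  grfdf <- data.frame(f_craniocaudal = grf$f_craniocaudal,
                      f_vertical = grf$f_vertical)
  tau <- inverse_dynamics(m, time, qmat, grfdf)
  tau_fun <- mousegait:::make_series_fun(
    time, as.matrix(tau[, mousegait:::sagittal_coords]))
  grf_fun <- mousegait:::make_series_fun(time, as.matrix(grfdf))
  dt <- time[2] - time[1]
  q0 <- vapply(qmat, `[`, numeric(1), 1)
  qd0 <- vapply(qmat, function(x) mousegait:::series_deriv(x, dt)[1],
                numeric(1))
  fwd <- forward_dynamics_torque(m, tau_fun, q0, qd0, range(time),
                                 grf_fun = grf_fun, times = time,
                                 rtol = 1e-6)
  rmse <- kinematic_rmse(fwd$time, fwd$q, time, qmat)
  expect_true(all(rmse < 1), info = paste(round(rmse, 3), collapse = ", "))
})

test_that("kinematic RMSE definition", {
  t <- seq(0, 1, 0.01)
  q1 <- data.frame(hip_flexion = sin(t))
  expect_equal(kinematic_rmse(t, q1, t, q1)[["hip_flexion"]], 0)
  q2 <- q1; q2$hip_flexion <- q2$hip_flexion + mousegait:::deg2rad(5)
  expect_equal(kinematic_rmse(t, q2, t, q1)[["hip_flexion"]], 5,
               tolerance = 1e-9)
  # sinusoidal difference of amplitude A -> A/sqrt(2)
  tfull <- seq(0, 1, length.out = 1001)
  q3 <- data.frame(hip_flexion = sin(2 * pi * tfull) *
                     mousegait:::deg2rad(6))
  q0 <- data.frame(hip_flexion = rep(0, length(tfull)))
  expect_equal(kinematic_rmse(tfull, q3, tfull, q0)[["hip_flexion"]],
               6 / sqrt(2), tolerance = 0.01)
})

test_that("short muscle-driven forward dynamics runs and bounds its state", {
  m <- test_model()
  exc <- function(t) stats::setNames(rep(0.3, length(m$mtus)),
                                     names(m$mtus))
  q0 <- test_pose()[mousegait:::sagittal_coords]
  fwd <- forward_dynamics_muscle(m, exc, q0, q0 * 0, c(0, 0.01),
                                 times = seq(0, 0.01, 0.002),
                                 grf_fun = NULL, rtol = 1e-4)
  expect_true(all(fwd$activations >= 0 & fwd$activations <= 1))
  expect_true(all(is.finite(fwd$q)))
  # zero excitation, no gravity, limits off, start at rest: equilibrium
  m0 <- test_model(); m0$gravity <- 0
  fwd0 <- forward_dynamics_muscle(
    m0, function(t) stats::setNames(rep(0, length(m0$mtus)),
                                    names(m0$mtus)),
    q0, q0 * 0, c(0, 0.01), times = seq(0, 0.01, 0.002),
    clfs = list(), rtol = 1e-6)
  expect_equal(max(abs(sweep(fwd0$q, 2, q0))), 0, tolerance = 1e-8)
})
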