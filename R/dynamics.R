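# Rigid-body dynamics of the sagittal hindlimb chain.
#
# The chain has four planar bodies -- pelvis+torso (rigidly joined),
# thigh, lower leg, foot -- actuated by the sagittal gencoords
# (pelvic_tilt, hip_flexion, knee_extension, ankle_flexion). The hip joint
# is the base point (the model's first, ground-to-body joint); its world
# trajectory may be prescribed. Hip adduction is handled as a decoupled
# frontal-plane single-DoF balance (the published data are 2-D sagittal).
#
# Inverse dynamics uses the virtual-work (Jacobian) form
#   tau_j = sum_i [ m_i (a_i - g) . J_i[,j] + I_i phidd_i S[i,j] ]
#           - J_cop[,j] . F_grf
# with CoM accelerations obtained by central differences of the forward
# kinematics on the (filtered) coordinate series. Forward dynamics builds
# M(q) and the bias vector from the same Jacobians.

# Gencoord -> absolute segment angle map (rows: pelvis+torso, thigh,
# lower_leg, foot; cols: pelvic_tilt, hip_flexion, knee_extension,
# ankle_flexion).
S_ANGLES <- rbind(c(1, 0, 0, 0),
                  c(1, 1, 0, 0),
                  c(1, 1, 1, 0),
                  c(1, 1, 1, -1))

rot2 <- function(phi) matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
drot2 <- function(phi) matrix(c(-sin(phi), cos(phi), -cos(phi), -sin(phi)), 2, 2)

# Planar mass properties of the four chain bodies (pelvis+torso combined).
planar_bodies <- function(model) {
  sg <- model$segments
  row <- function(nm) sg[sg$name == nm, ]
  p <- row("pelvis"); t <- row("torso")
  m1 <- p$mass + t$mass
  c1 <- if (m1 > 0)
    (p$mass * c(p$chain_x, p$chain_y) + t$mass * c(t$chain_x, t$chain_y)) / m1
  else c(0, 0)
  I1 <- p$izz + p$mass * sum((c(p$chain_x, p$chain_y) - c1)^2) +
    t$izz + t$mass * sum((c(t$chain_x, t$chain_y) - c1)^2)
  th <- row("thigh"); ll <- row("lower_leg"); ft <- row("foot")
  list(
    mass = c(m1, th$mass, ll$mass, ft$mass),
    inertia = c(I1, th$izz, ll$izz, ft$izz),
    com = rbind(c1, c(th$chain_x, th$chain_y), c(ll$chain_x, ll$chain_y),
                c(ft$chain_x, ft$chain_y)),
    lengths = c(NA, row("thigh")$length, row("lower_leg")$length,
                row("foot")$length)
  )
}

# Forward kinematics + Jacobians of the planar chain at sagittal pose q4
# (named or ordered pelvic_tilt, hip_flexion, knee_extension, ankle_flexion).
fk_planar <- function(model, q4, base = c(0, 0), cop_offset = 0,
                      bodies = planar_bodies(model)) {
  q4 <- sagittal_pose(q4)
  phi <- drop(S_ANGLES %*% q4) + c(0, -pi / 2, -pi / 2, -pi / 2)
  coms <- matrix(0, 2, 4)
  Jcom <- vector("list", 4)
  origin <- base
  Jorigin <- matrix(0, 2, 4)
  origins <- matrix(0, 2, 4)
  for (k in 1:4) {
    origins[, k] <- origin
    Rk <- rot2(phi[k]); dRk <- drot2(phi[k])
    ck <- bodies$com[k, ]
    coms[, k] <- origin + Rk %*% ck
    Jcom[[k]] <- Jorigin + (dRk %*% ck) %*% t(S_ANGLES[k, ])
    if (k < 4) {
      # distal joint of body k+? : bodies 2..4 are the limb segments
      if (k >= 2) {
        dvec <- c(0, -bodies$lengths[k])
        origin <- origin + Rk %*% dvec
        Jorigin <- Jorigin + (dRk %*% dvec) %*% t(S_ANGLES[k, ])
      }
      # body 1 (pelvis) shares the hip origin with the thigh: no update
    }
  }
  cop2 <- model$foot_cop[1:2] + c(0, -cop_offset)
  R4 <- rot2(phi[4]); dR4 <- drot2(phi[4])
  x_cop <- origins[, 4] + R4 %*% cop2
  J_cop <- Jorigin + (dR4 %*% cop2) %*% t(S_ANGLES[4, ])
  mtp <- origins[, 4] + R4 %*% c(0, -bodies$lengths[4])
  list(phi = phi, coms = coms, Jcom = Jcom, origins = origins,
       x_cop = drop(x_cop), J_cop = J_cop, mtp = drop(mtp))
}

sagittal_pose <- function(q) {
  if (!is.null(names(q))) {
    out <- stats::setNames(numeric(4), sagittal_coords)
    keep <- intersect(names(q), sagittal_coords)
    out[keep] <- q[keep]
    out
  } else {
    if (length(q) != 4)
      stop_mousegait("mousegait_input_error",
                     "unnamed sagittal pose must have 4 values")
    stats::setNames(as.numeric(q), sagittal_coords)
  }
}

# Mass matrix and velocity/gravity bias of the sagittal chain.
chain_mass_matrix <- function(model, q4, bodies = planar_bodies(model)) {
  fk <- fk_planar(model, q4, bodies = bodies)
  M <- matrix(0, 4, 4)
  for (k in 1:4) {
    J <- fk$Jcom[[k]]
    M <- M + bodies$mass[k] * crossprod(J) +
      bodies$inertia[k] * tcrossprod(S_ANGLES[k, ])
  }
  M
}

chain_bias <- function(model, q4, qd4, bodies = planar_bodies(model),
                       eps = 1e-6) {
  # b_j = sum_i m_i (Jdot_i qd - g) . J_i[,j]; Jdot qd via directional
  # finite difference of the Jacobians along qd.
  q4 <- sagittal_pose(q4)
  fk0 <- fk_planar(model, q4, bodies = bodies)
  fkp <- fk_planar(model, q4 + eps * qd4, bodies = bodies)
  fkm <- fk_planar(model, q4 - eps * qd4, bodies = bodies)
  gvec <- c(0, -model$gravity)
  b <- numeric(4)
  for (k in 1:4) {
    Jd_qd <- ((fkp$Jcom[[k]] - fkm$Jcom[[k]]) / (2 * eps)) %*% qd4
    b <- b + bodies$mass[k] *
      drop(t(fk0$Jcom[[k]]) %*% (Jd_qd - gvec))
  }
  b
}

#' Inverse dynamics of the sagittal hindlimb chain
#'
#' Net generalized moments at every sample that reproduce the measured
#' kinematics under the applied ground reaction force:
#' `tau = M(q) qdd + c(q, qd) + g(q) - J_cop^T F_grf`, computed in
#' virtual-work form with accelerations from central differences of the
#' (filtered) coordinate series. Hip adduction, when present in `q`, is
#' solved as a decoupled frontal-plane single-DoF balance.
#'
#' @param model a `hindlimb_model`.
#' @param time sample times, s (uniform).
#' @param q data.frame/matrix of gencoord series (radians) with columns
#'   named by coordinate; sagittal coordinates are required, `hip_adduction`
#'   optional.
#' @param grf data.frame with `f_craniocaudal`, `f_vertical` (N) on the
#'   same time base (zero during swing), or NULL for no external load.
#' @param cop_offset cranial(+) CoP shift along the foot axis, m.
#' @param base n x 2 matrix of world hip positions (default fixed at the
#'   origin; a moving base contributes its acceleration to the inertial
#'   terms).
#' @return object of class `joint_moment_series`: data.frame `time` plus one
#'   moment column per coordinate, N m (multiply by 1000 for the reported
#'   N mm).
#' @export
inverse_dynamics <- function(model, time, q, grf = NULL, cop_offset = 0,
                             base = NULL) {
  q <- as.data.frame(q)
  n <- length(time)
  if (n < 50)
    warning("fewer than 50 samples per stride; ",
            "numerical differentiation may be unstable")
  dt <- diff(time)
  if (max(abs(dt - dt[1])) > 1e-9 * max(abs(dt)))
    stop_mousegait("mousegait_input_error", "time base must be uniform")
  dt <- dt[1]
  bodies <- planar_bodies(model)
  if (is.null(base)) base <- matrix(0, n, 2)
  fks <- lapply(seq_len(n), function(i) {
    q4 <- stats::setNames(as.numeric(q[i, sagittal_coords]), sagittal_coords)
    fk_planar(model, q4, base = base[i, ], cop_offset = cop_offset,
              bodies = bodies)
  })
  # CoM accelerations by double central differences of FK positions
  acc <- lapply(1:4, function(k) {
    xy <- t(vapply(fks, function(f) f$coms[, k], numeric(2)))
    cbind(series_deriv(series_deriv(xy[, 1], dt), dt),
          series_deriv(series_deriv(xy[, 2], dt), dt))
  })
  qdd4 <- vapply(sagittal_coords,
                 function(cc) series_deriv(series_deriv(q[[cc]], dt), dt),
                 numeric(n))
  phidd <- qdd4 %*% t(S_ANGLES)
  gvec <- c(0, -model$gravity)
  tau <- matrix(0, n, 4, dimnames = list(NULL, sagittal_coords))
  has_grf <- !is.null(grf)
  for (i in seq_len(n)) {
    fk <- fks[[i]]
    ti <- numeric(4)
    for (k in 1:4) {
      ti <- ti + bodies$mass[k] *
        drop(t(fk$Jcom[[k]]) %*% (acc[[k]][i, ] - gvec)) +
        bodies$inertia[k] * phidd[i, k] * S_ANGLES[k, ]
    }
    if (has_grf) {
      F <- c(grf$f_craniocaudal[i], grf$f_vertical[i])
      ti <- ti - drop(t(fk$J_cop) %*% F)
    }
    tau[i, ] <- ti
  }
  out <- data.frame(time = time, tau)
  if ("hip_adduction" %in% names(q)) {
    out$hip_adduction <- adduction_moment(model, time, q, grf, fks, bodies)
  }
  class(out) <- c("joint_moment_series", "data.frame")
  out
}

# Decoupled frontal-plane hip-adduction balance: limb segments as a
# composite pendulum about the hip's cranial axis, with the vertical GRF
# supporting the abducted limb at the CoP lever. An approximation, since
# full 3-D dynamics are unidentifiable from 2-D sagittal data.
adduction_moment <- function(model, time, q, grf, fks, bodies) {
  n <- length(time)
  dt <- time[2] - time[1]
  qa <- q[["hip_adduction"]]
  qadd <- series_deriv(series_deriv(qa, dt), dt)
  sg <- model$segments
  ixx <- stats::setNames(sg$ixx, sg$name)
  tau <- numeric(n)
  for (i in seq_len(n)) {
    fk <- fks[[i]]
    hip <- fk$origins[, 1]
    d <- sqrt(colSums((fk$coms[, 2:4] - hip)^2))
    Ix <- sum(ixx[c("thigh", "lower_leg", "foot")] +
                bodies$mass[2:4] * d^2)
    grav <- sum(bodies$mass[2:4] * d) * model$gravity * sin(qa[i])
    lever <- sqrt(sum((fk$x_cop - hip)^2))
    fz <- if (is.null(grf)) 0 else grf$f_vertical[i]
    tau[i] <- Ix * qadd[i] + grav - fz * lever * sin(qa[i])
  }
  tau
}

#' Convert a joint moment series to N mm
#'
#' @param moments a `joint_moment_series` (N m).
#' @return data.frame with moments in N mm (exactly x1000).
#' @export
moments_nmm <- function(moments) {
  out <- as.data.frame(moments)
  for (cc in setdiff(names(out), "time")) out[[cc]] <- out[[cc]] * 1000
  out
}

#' Sensitivity of joint moments to the center-of-pressure location
#'
#' Re-runs [inverse_dynamics()] with the CoP shifted along the foot's
#' cranial-caudal axis and reports, per coordinate, the change of the
#' peak-magnitude stance moment relative to the unshifted run.
#'
#' @inheritParams inverse_dynamics
#' @param offsets CoP shifts, m (cranial positive).
#' @return list with `moments` (one `joint_moment_series` per offset, named
#'   by offset) and `deltas` (data.frame offset x coordinate, N m).
#' @export
cop_sensitivity <- function(model, time, q, grf, offsets = c(-0.002, 0.002),
                            base = NULL) {
  offsets <- union(0, offsets)
  runs <- lapply(offsets, function(o)
    inverse_dynamics(model, time, q, grf, cop_offset = o, base = base))
  names(runs) <- sprintf("%+g", offsets)
  stance <- if (is.null(grf)) rep(TRUE, length(time))
            else abs(grf$f_vertical) > 1e-12
  coords <- setdiff(names(runs[[1]]), "time")
  peak <- function(m) {
    vapply(coords, function(cc) {
      v <- m[[cc]][stance]
      if (!length(v)) return(0)
      v[which.max(abs(v))]
    }, numeric(1))
  }
  base_peak <- peak(runs[[which(offsets == 0)]])
  deltas <- t(vapply(runs, function(m) peak(m) - base_peak,
                     numeric(length(coords))))
  deltas <- data.frame(offset = offsets, deltas)
  list(moments = runs[order(offsets)], deltas = deltas[order(offsets), ])
}

#' Coordinate limit force
#'
#' Passive restraining moment engaging when a coordinate exceeds its limits:
#' zero well inside the range, a linear restoring stiffness beyond a limit
#' (quadratically smoothed across `transition_width` around the limit) plus
#' a damping term opposing velocity while engaged.
#'
#' @param clf list with `lower`, `upper` (rad), `stiffness` (N m/rad),
#'   `damping` (N m s/rad), `transition_width` (rad).
#' @param q coordinate value, rad.
#' @param qdot coordinate velocity, rad/s.
#' @return limit moment, N m.
#' @export
limit_moment <- function(clf, q, qdot = 0) {
  w <- clf$transition_width
  blend <- function(e) {
    # 0 for e < -w, (e+w)^2/(4w) on [-w, w], e beyond; C1 everywhere
    ifelse(e <= -w, 0, ifelse(e >= w, e, (e + w)^2 / (4 * w)))
  }
  dblend <- function(e) ifelse(e <= -w, 0, ifelse(e >= w, 1, (e + w) / (2 * w)))
  e_up <- q - clf$upper
  e_lo <- clf$lower - q
  engage <- pmax(dblend(e_up), dblend(e_lo))
  -clf$stiffness * blend(e_up) + clf$stiffness * blend(e_lo) -
    clf$damping * qdot * engage
}

#' Default coordinate limit forces for a model
#'
#' One limit force per unlocked coordinate, limits at the coordinate ranges.
#'
#' @param model a `hindlimb_model`.
#' @param stiffness N m/rad (default 0.5).
#' @param damping N m s/rad (default 0.01).
#' @param transition_width rad (default 2 degrees).
#' @return named list of limit-force parameter lists.
#' @export
default_limit_forces <- function(model, stiffness = 0.5, damping = 0.01,
                                 transition_width = deg2rad(2)) {
  co <- model$coordinates
  out <- lapply(seq_len(nrow(co)), function(i)
    list(coordinate = co$name[i], lower = co$lower[i], upper = co$upper[i],
         stiffness = stiffness, damping = damping,
         transition_width = transition_width))
  stats::setNames(out, co$name)
}

# --- Adaptive Dormand-Prince RK45 integrator -------------------------------

#' Adaptive explicit Runge-Kutta integration (Dormand-Prince 5(4))
#'
#' General-purpose ODE solver used by the forward-dynamics tools (no ODE
#' package is assumed in the runtime environment). Dense output at `times`
#' by cubic Hermite interpolation between accepted steps.
#'
#' @param f derivative function `f(t, y) -> dy/dt`.
#' @param t_span `c(t0, t1)`.
#' @param y0 initial state.
#' @param times output times (default 101 points over `t_span`).
#' @param rtol,atol relative/absolute tolerances.
#' @param max_steps step-count guard.
#' @return list with `time`, `y` (length(times) x length(y0) matrix),
#'   `n_steps`, `success`, and on failure `last_t`, `last_y`.
#' @export
ode_rk45 <- function(f, t_span, y0, times = NULL, rtol = 1e-6, atol = 1e-9,
                     max_steps = 100000L) {
  # Dormand-Prince coefficients
  A <- list(c(1/5),
            c(3/40, 9/40),
            c(44/45, -56/15, 32/9),
            c(19372/6561, -25360/2187, 64448/6561, -212/729),
            c(9017/3168, -355/33, 46732/5247, 49/176, -5103/18656),
            c(35/384, 0, 500/1113, 125/192, -2187/6784, 11/84))
  cc <- c(1/5, 3/10, 4/5, 8/9, 1, 1)
  b5 <- c(35/384, 0, 500/1113, 125/192, -2187/6784, 11/84, 0)
  b4 <- c(5179/57600, 0, 7571/16695, 393/640, -92097/339200, 187/2100, 1/40)
  t0 <- t_span[1]; t1 <- t_span[2]
  if (is.null(times)) times <- seq(t0, t1, length.out = 101)
  h <- (t1 - t0) / 100
  t <- t0; y <- y0
  k1 <- f(t, y)
  ts <- t; ys <- list(y); ds <- list(k1)
  n_steps <- 0L
  while (t < t1 - 1e-14 * abs(t1)) {
    if (n_steps >= max_steps)
      return(list(success = FALSE, last_t = t, last_y = y,
                  message = "max step count exceeded",
                  time = ts, n_steps = n_steps))
    h <- min(h, t1 - t)
    K <- matrix(0, length(y), 7)
    K[, 1] <- k1
    for (s in 1:6) {
      yi <- y + h * drop(K[, 1:s, drop = FALSE] %*% A[[s]])
      K[, s + 1] <- f(t + cc[s] * h, yi)
    }
    y5 <- y + h * drop(K %*% b5)
    y4 <- y + h * drop(K %*% b4)
    sc <- atol + rtol * pmax(abs(y), abs(y5))
    err <- sqrt(mean(((y5 - y4) / sc)^2))
    if (!is.finite(err)) err <- 2
    if (err <= 1) {
      t <- t + h
      y <- y5
      k1 <- K[, 7]   # FSAL
      ts <- c(ts, t); ys <- c(ys, list(y)); ds <- c(ds, list(k1))
    }
    h <- h * min(5, max(0.2, 0.9 * (1 / max(err, 1e-10))^(1/5)))
    n_steps <- n_steps + 1L
  }
  Y <- do.call(rbind, ys)
  D <- do.call(rbind, ds)
  out <- matrix(NA_real_, length(times), length(y0))
  idx <- findInterval(times, ts, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), length(ts) - 1L)
  for (i in seq_along(times)) {
    j <- idx[i]
    if (length(ts) == 1L) { out[i, ] <- Y[1, ]; next }
    hseg <- ts[j + 1] - ts[j]
    s <- (times[i] - ts[j]) / hseg
    h00 <- 2 * s^3 - 3 * s^2 + 1; h10 <- s^3 - 2 * s^2 + s
    h01 <- -2 * s^3 + 3 * s^2; h11 <- s^3 - s^2
    out[i, ] <- h00 * Y[j, ] + h10 * hseg * D[j, ] +
      h01 * Y[j + 1, ] + h11 * hseg * D[j + 1, ]
  }
  list(time = times, y = out, n_steps = n_steps, success = TRUE)
}

#' Torque-driven forward dynamics of the sagittal chain
#'
#' Integrates the chain under prescribed generalized moments (plus optional
#' GRF and coordinate limit forces). The central consistency property is
#' that driving this with the moments from [inverse_dynamics()] reproduces
#' the input kinematics.
#'
#' @param model a `hindlimb_model`.
#' @param tau_fun function `(t) -> length-4 sagittal moment vector`, N m.
#' @param q0,qd0 initial sagittal pose/velocity (named or ordered).
#' @param t_span integration interval, s.
#' @param grf_fun optional `(t) -> c(f_craniocaudal, f_vertical)`, N.
#' @param cop_offset CoP shift, m.
#' @param clfs optional list of coordinate limit forces
#'   ([default_limit_forces()]).
#' @param times output times.
#' @param rtol integrator relative tolerance (default 1e-6).
#' @param locked coordinate labels held fixed at their initial values
#'   (useful for reduced models whose mass matrix would otherwise be
#'   singular).
#' @return list with `time`, `q` and `qd` matrices (columns = sagittal
#'   coordinates), `success`.
#' @export
forward_dynamics_torque <- function(model, tau_fun, q0, qd0, t_span,
                                    grf_fun = NULL, cop_offset = 0,
                                    clfs = NULL, times = NULL, rtol = 1e-6,
                                    locked = NULL) {
  bodies <- planar_bodies(model)
  q0 <- sagittal_pose(q0); qd0 <- sagittal_pose(qd0)
  free <- !(sagittal_coords %in% locked)
  rhs <- function(t, y) {
    q4 <- y[1:4]; qd4 <- y[5:8]
    tau <- as.numeric(tau_fun(t))
    if (!is.null(clfs)) {
      for (j in seq_along(sagittal_coords)) {
        clf <- clfs[[sagittal_coords[j]]]
        if (!is.null(clf)) tau[j] <- tau[j] + limit_moment(clf, q4[j], qd4[j])
      }
    }
    if (!is.null(grf_fun)) {
      F <- grf_fun(t)
      if (any(F != 0)) {
        fk <- fk_planar(model, q4, cop_offset = cop_offset, bodies = bodies)
        tau <- tau + drop(t(fk$J_cop) %*% F)
      }
    }
    M <- chain_mass_matrix(model, q4, bodies)
    b <- chain_bias(model, q4, qd4, bodies)
    qdd <- numeric(4)
    qdd[free] <- solve(M[free, free, drop = FALSE], (tau - b)[free])
    qd_out <- qd4
    qd_out[!free] <- 0
    c(qd_out, qdd)
  }
  sol <- ode_rk45(rhs, t_span, c(q0, qd0), times = times, rtol = rtol)
  if (!sol$success)
    stop_mousegait("mousegait_integration_failure",
                   paste("forward dynamics failed:", sol$message),
                   last_t = sol$last_t, last_y = sol$last_y)
  q <- sol$y[, 1:4, drop = FALSE]; qd <- sol$y[, 5:8, drop = FALSE]
  colnames(q) <- colnames(qd) <- sagittal_coords
  list(time = sol$time, q = q, qd = qd, success = TRUE,
       n_steps = sol$n_steps)
}

#' Muscle-driven forward dynamics
#'
#' Integrates the sagittal chain driven by the model's MTUs under prescribed
#' excitations, with first-order excitation-activation dynamics (10/40 ms
#' default time constants), rigid-tendon muscle forces, prescribed reserve
#' moments, coordinate limit forces and the measured GRF (CoP fixed in the
#' foot frame). The simulation is not constrained to the experimental
#' kinematics.
#'
#' @param model a `hindlimb_model`.
#' @param excitation_fun function `(t) -> named activation-target vector`
#'   over MTU labels, values in `[0, 1]`.
#' @param q0,qd0 initial sagittal state.
#' @param a0 initial activations (named over MTUs; default 0).
#' @param t_span integration interval.
#' @param reserve_fun optional `(t) -> length-4 sagittal reserve moments`,
#'   N m (e.g. from a static-optimization solution).
#' @param grf_fun,cop_offset,clfs,times,rtol as in
#'   [forward_dynamics_torque()].
#' @param act_params [activation_dynamics_params()].
#' @param curves [default_muscle_curves()].
#' @return list with `time`, `q`, `qd`, `activations` matrices.
#' @export
forward_dynamics_muscle <- function(model, excitation_fun, q0, qd0,
                                    t_span, a0 = NULL, reserve_fun = NULL,
                                    grf_fun = NULL, cop_offset = 0,
                                    clfs = default_limit_forces(model),
                                    times = NULL, rtol = 1e-5,
                                    act_params = activation_dynamics_params(),
                                    curves = default_muscle_curves()) {
  bodies <- planar_bodies(model)
  labels <- names(model$mtus)
  nm <- length(labels)
  cache <- mtu_geometry_cache(model)
  par <- mtu_param_matrix(model)
  q0 <- sagittal_pose(q0); qd0 <- sagittal_pose(qd0)
  if (is.null(a0)) a0 <- stats::setNames(rep(0, nm), labels)
  rhs <- function(t, y) {
    q4 <- y[1:4]; qd4 <- y[5:8]
    a <- pmin(pmax(y[8 + seq_len(nm)], 0), 1)
    qfull <- complete_pose(model, stats::setNames(q4, sagittal_coords))
    R <- all_moment_arms(model, qfull, sagittal_coords, cache)
    L <- all_mtu_lengths(model, qfull, cache)
    V <- -drop(R %*% qd4)
    F <- rigid_forces_bulk(par, curves, a, L, V)
    tau <- drop(t(R) %*% F)
    if (!is.null(reserve_fun)) tau <- tau + as.numeric(reserve_fun(t))
    for (j in seq_along(sagittal_coords)) {
      clf <- clfs[[sagittal_coords[j]]]
      if (!is.null(clf)) tau[j] <- tau[j] + limit_moment(clf, q4[j], qd4[j])
    }
    if (!is.null(grf_fun)) {
      F <- grf_fun(t)
      if (any(F != 0)) {
        fk <- fk_planar(model, q4, cop_offset = cop_offset, bodies = bodies)
        tau <- tau + drop(t(fk$J_cop) %*% F)
      }
    }
    M <- chain_mass_matrix(model, q4, bodies)
    b <- chain_bias(model, q4, qd4, bodies)
    qdd <- solve(M, tau - b)
    u <- pmin(pmax(as.numeric(excitation_fun(t)[labels]), 0), 1)
    tau_a <- ifelse(u > a, act_params$tau_act, act_params$tau_deact)
    dadt <- (u - a) / tau_a
    dadt[a >= 1 & dadt > 0] <- 0
    dadt[a <= 0 & dadt < 0] <- 0
    c(qd4, qdd, dadt)
  }
  sol <- ode_rk45(rhs, t_span, c(q0, qd0, a0), times = times, rtol = rtol,
                  atol = 1e-8)
  if (!sol$success)
    stop_mousegait("mousegait_integration_failure",
                   paste("muscle-driven forward dynamics failed:",
                         sol$message),
                   last_t = sol$last_t, last_y = sol$last_y)
  q <- sol$y[, 1:4, drop = FALSE]; qd <- sol$y[, 5:8, drop = FALSE]
  acts <- pmin(pmax(sol$y[, 8 + seq_len(nm), drop = FALSE], 0), 1)
  colnames(q) <- colnames(qd) <- sagittal_coords
  colnames(acts) <- labels
  list(time = sol$time, q = q, qd = qd, activations = acts,
       n_steps = sol$n_steps)
}

#' Moment-arm matrix of all MTUs about a set of coordinates
#'
#' @param model a `hindlimb_model`.
#' @param q full named pose.
#' @param coords coordinate labels (default all).
#' @param step finite-difference step, rad.
#' @return matrix (MTUs x coordinates) of moment arms, m.
#' @export
moment_arm_matrix <- function(model, q, coords = coordinate_order,
                              step = 1e-5) {
  q <- complete_pose(model, q)
  labels <- names(model$mtus)
  R <- matrix(0, length(labels), length(coords),
              dimnames = list(labels, coords))
  for (cc in coords) {
    qp <- qm <- q
    qp[cc] <- qp[cc] + step
    qm[cc] <- qm[cc] - step
    Tp <- segment_transforms(model, qp)
    Tm <- segment_transforms(model, qm)
    for (i in seq_along(labels)) {
      path <- model$mtus[[labels[i]]]$path
      if (!cc %in% path$spanned) next
      R[i, cc] <- -(path_length_T(path, Tp) - path_length_T(path, Tm)) /
        (2 * step)
    }
  }
  R
}

path_length_T <- function(path, Ts) {
  via <- path$via
  pts <- matrix(0, 3, nrow(via))
  for (i in seq_len(nrow(via)))
    pts[, i] <- drop(happly(Ts[[via$segment[i]]],
                            c(via$x[i], via$y[i], via$z[i])))
  sum(sqrt(rowSums(diff(t(pts))^2)))
}

#' Root-mean-squared kinematic error per coordinate
#'
#' Resamples the simulated series onto the reference time base by cubic
#' spline and reports the pointwise RMS difference in degrees.
#'
#' @param t_sim,q_sim simulated time base and coordinate matrix (radians).
#' @param t_ref,q_ref reference time base and coordinate matrix (radians),
#'   sharing column names with `q_sim`.
#' @return named vector of RMS errors, degrees.
#' @export
kinematic_rmse <- function(t_sim, q_sim, t_ref, q_ref) {
  q_sim <- as.data.frame(q_sim); q_ref <- as.data.frame(q_ref)
  coords <- intersect(names(q_sim), names(q_ref))
  vapply(coords, function(cc) {
    si <- stats::spline(t_sim, q_sim[[cc]], xout = t_ref, method = "fmm")$y
    rad2deg(sqrt(mean((si - q_ref[[cc]])^2)))
  }, numeric(1))
}
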