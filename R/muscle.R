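# Hill-type musculotendon mechanics.
#
# Each MTU is a Hill-type actuator: a contractile fiber (active force-length,
# force-velocity, passive force-length properties, pennated at constant
# thickness) in series with a tendon that is slack below `l_ts`. Two modes
# are provided: a rigid-tendon mode (all length change in the fiber; passive
# fiber force omitted -- the static-optimization simplification) and a
# compliant-tendon mode (fiber-tendon force balance solved at each call;
# passive fiber force included) used by the muscle-analysis work pipeline.

#' Generic muscle curve set
#'
#' Smooth parametric force-length / force-velocity / tendon curves with
#' documented, configurable shape constants. All curves are normalized:
#' lengths by optimal fiber length, velocities by `v_max * l_opt`, forces by
#' `f_max`.
#'
#' * active force-length: Gaussian `exp(-((l - 1)/fl_width)^2)`, peak 1 at
#'   normalized length 1;
#' * passive force-length: `(exp(kpe (l - 1)/e0_pe) - 1)/(exp(kpe) - 1)`,
#'   zero at or below optimal length, 1 at strain `e0_pe`;
#' * force-velocity: Hill hyperbola `(1 + v)/(1 - v/af)` for shortening
#'   (normalized fiber velocity `v` in `[-1, 0]`, zero at maximal shortening)
#'   joined C1-continuously to an eccentric saturation at `flen_max`;
#' * tendon force-strain: `(exp(kt e/e0_t) - 1)/(exp(kt) - 1)`, zero at or
#'   below the slack length, 1 (i.e. `f_max`) at strain `e0_t`.
#'
#' @param fl_width active force-length width (default 0.45).
#' @param kpe,e0_pe passive-curve exponent and strain at `f_max`
#'   (defaults 4, 0.6).
#' @param af force-velocity curvature (default 0.25).
#' @param flen_max eccentric plateau (default 1.4).
#' @param kt,e0_t tendon-curve exponent and strain at `f_max`
#'   (defaults 3, 0.049).
#' @return an object of class `muscle_curves`: list of vectorized functions
#'   `active_fl`, `passive_fl`, `fv`, `tendon_fs` plus the constants.
#' @export
default_muscle_curves <- function(fl_width = 0.45, kpe = 4, e0_pe = 0.6,
                                  af = 0.25, flen_max = 1.4,
                                  kt = 3, e0_t = 0.049) {
  stopifnot(fl_width > 0, e0_pe > 0, af > 0, flen_max > 1, e0_t > 0)
  slope0 <- 1 + 1 / af                       # concentric slope at v = 0
  ke <- slope0 / (flen_max - 1)              # eccentric rate for C1 join
  structure(list(
    active_fl = function(l) exp(-((l - 1) / fl_width)^2),
    passive_fl = function(l) {
      f <- (exp(kpe * (l - 1) / e0_pe) - 1) / (exp(kpe) - 1)
      ifelse(l > 1, f, 0)
    },
    fv = function(v) {
      conc <- (1 + pmax(v, -1)) / (1 - pmax(v, -1) / af)
      ecc <- flen_max - (flen_max - 1) * exp(-ke * v)
      ifelse(v < 0, ifelse(v <= -1, 0, conc), ecc)
    },
    tendon_fs = function(e) {
      # exponential toe region up to e0_t, then linear continuation with the
      # toe-end slope (keeps the curve monotone and finite for any strain)
      slope_end <- kt * exp(kt) / (e0_t * (exp(kt) - 1))
      f <- ifelse(e <= e0_t,
                  (exp(kt * pmin(e, e0_t) / e0_t) - 1) / (exp(kt) - 1),
                  1 + slope_end * (e - e0_t))
      ifelse(e > 0, f, 0)
    },
    constants = list(fl_width = fl_width, kpe = kpe, e0_pe = e0_pe, af = af,
                     flen_max = flen_max, kt = kt, e0_t = e0_t)
  ), class = "muscle_curves")
}

#' Fiber state under the rigid-tendon assumption
#'
#' With a rigid tendon of length `l_ts` and a constant-thickness pennation
#' model (`w = l_opt * sin(pennation0)`), the fiber length and velocity
#' follow directly from the MTU length and velocity.
#'
#' @param p MTU parameter list with `l_opt`, `l_ts`, `pennation0` (degrees),
#'   `v_max` (one element of `model$mtus[[..]]$params`, or any list with
#'   those fields).
#' @param l_mtu MTU length, m.
#' @param v_mtu MTU lengthening velocity, m/s.
#' @return list with `fiber_length` (m), `cos_pennation`, `fiber_velocity`
#'   (m/s), `norm_fiber_length`, `norm_fiber_velocity`.
#' @export
rigid_tendon_fiber_state <- function(p, l_mtu, v_mtu = 0) {
  if (l_mtu <= p$l_ts * (1 - 1e-6))
    stop_mousegait("mousegait_slack_tendon",
                   sprintf("MTU length %.6g m at or below tendon slack length %.6g m",
                           l_mtu, p$l_ts))
  w <- p$l_opt * sin(deg2rad(p$pennation0))
  proj <- max(l_mtu - p$l_ts, 0)
  lf <- max(sqrt(proj^2 + w^2), 1e-12)
  cosa <- proj / lf
  vf <- v_mtu * cosa
  list(fiber_length = lf, cos_pennation = cosa, fiber_velocity = vf,
       norm_fiber_length = lf / p$l_opt,
       norm_fiber_velocity = vf / (p$v_max * p$l_opt))
}

#' Tendon-line force of an MTU
#'
#' Rigid mode: `F = f_max * a * FL(l) * FV(v) * cos(pennation)` with the
#' passive fiber term omitted (the static-optimization simplification).
#' Compliant mode: the fiber length is found from the fiber-tendon force
#' balance (passive fiber force included; the force-velocity multiplier is
#' evaluated at the rigid-tendon fiber velocity) and the returned force is
#' the tendon curve force at equilibrium.
#'
#' A slack tendon (`l_mtu <= l_ts`) contributes zero force.
#'
#' @param p MTU parameter list (see [rigid_tendon_fiber_state()]), needs
#'   `f_max` too.
#' @param curves a `muscle_curves` object.
#' @param a activation in `[0, 1]`.
#' @param l_mtu MTU length, m.
#' @param v_mtu MTU lengthening velocity, m/s.
#' @param mode `"rigid"` or `"compliant"`.
#' @param tol relative tolerance of the compliant force balance.
#' @return tendon-line force, N (non-negative).
#' @export
mtu_force <- function(p, curves, a, l_mtu, v_mtu = 0,
                      mode = c("rigid", "compliant"), tol = 1e-9) {
  mode <- match.arg(mode)
  if (a < 0 || a > 1)
    stop_mousegait("mousegait_input_error", "activation must be in [0, 1]")
  if (l_mtu <= p$l_ts) return(0)
  st <- rigid_tendon_fiber_state(p, l_mtu, v_mtu)
  if (mode == "rigid") {
    F <- p$f_max * a * curves$active_fl(st$norm_fiber_length) *
      curves$fv(st$norm_fiber_velocity) * st$cos_pennation
    return(max(F, 0))
  }
  # Compliant: solve for fiber length lf in the force balance
  #   f_t(strain(l_t)) = (a FL(lf~) FV + FP(lf~)) cos(pennation(lf))
  # with l_t = l_mtu - sqrt(lf^2 - w^2) and constant fiber thickness w.
  w <- p$l_opt * sin(deg2rad(p$pennation0))
  fv_mult <- curves$fv(st$norm_fiber_velocity)
  bal <- function(lf) {
    proj <- sqrt(max(lf^2 - w^2, 0))
    lt <- l_mtu - proj
    cosa <- if (lf > 0) proj / lf else 0
    ft <- curves$tendon_fs((lt - p$l_ts) / p$l_ts)
    fm <- (a * curves$active_fl(lf / p$l_opt) * fv_mult +
             curves$passive_fl(lf / p$l_opt)) * cosa
    ft - fm
  }
  lo <- w + 1e-9 * p$l_opt
  hi <- sqrt(l_mtu^2 + w^2)
  flo <- bal(lo); fhi <- bal(hi)
  if (flo <= 0) return(0)  # no tendon tension even with zero fiber force
  if (fhi > 0) {
    # tendon still taut with the fiber absorbing the whole MTU length --
    # equilibrium is at the bracket end (numerically degenerate input)
    stop_mousegait("mousegait_equilibrium_failure",
                   sprintf("compliant-tendon balance not bracketed for MTU (a=%.3g, l_mtu=%.6g)",
                           a, l_mtu))
  }
  r <- stats::uniroot(bal, c(lo, hi), tol = tol * p$l_opt)
  lf <- r$root
  lt <- l_mtu - sqrt(max(lf^2 - w^2, 0))
  max(p$f_max * curves$tendon_fs((lt - p$l_ts) / p$l_ts), 0)
}

#' First-order excitation-activation dynamics parameters
#'
#' @param tau_act activation time constant, s (default 0.010).
#' @param tau_deact deactivation time constant, s (default 0.040).
#' @return list with `tau_act`, `tau_deact`.
#' @export
activation_dynamics_params <- function(tau_act = 0.010, tau_deact = 0.040) {
  stopifnot(tau_act > 0, tau_deact > 0)
  list(tau_act = tau_act, tau_deact = tau_deact)
}

#' One step of first-order excitation-activation dynamics
#'
#' Integrates `da/dt = (u - a)/tau` exactly over `dt`, with
#' `tau = tau_act` when the excitation exceeds the activation and
#' `tau_deact` otherwise; the result is clamped to `[0, 1]`.
#'
#' @param a current activation.
#' @param u excitation in `[0, 1]`.
#' @param dt time step, s.
#' @param p parameters from [activation_dynamics_params()].
#' @return updated activation.
#' @export
activation_step <- function(a, u, dt, p = activation_dynamics_params()) {
  if (dt <= 0)
    stop_mousegait("mousegait_input_error", "dt must be positive")
  tau <- ifelse(u > a, p$tau_act, p$tau_deact)
  out <- a + (u - a) * (1 - exp(-dt / tau))
  pmin(pmax(out, 0), 1)
}

#' Simulate activation under a sampled excitation trajectory
#'
#' @param time sample times, s (strictly increasing).
#' @param u excitation samples in `[0, 1]`.
#' @param a0 initial activation.
#' @param p parameters from [activation_dynamics_params()].
#' @return activation at every sample time.
#' @export
simulate_activation <- function(time, u, a0 = 0,
                                p = activation_dynamics_params()) {
  stopifnot(length(time) == length(u))
  a <- numeric(length(time))
  a[1] <- min(max(a0, 0), 1)
  for (i in seq_along(time)[-1])
    a[i] <- activation_step(a[i - 1], u[i - 1], time[i] - time[i - 1], p)
  a
}

#' Export muscle curves as tabulated samples
#'
#' Writes `(x, y)` samples of each curve to a tab-delimited file for plotting
#' and cross-checking.
#'
#' @param curves a `muscle_curves` object.
#' @param path output file.
#' @param n samples per curve.
#' @return the sampled data.frame, invisibly.
#' @export
write_curve_table <- function(curves, path, n = 200) {
  grid <- list(
    active_force_length = list(x = seq(0.2, 1.8, length.out = n),
                               f = curves$active_fl),
    passive_force_length = list(x = seq(0.8, 1.8, length.out = n),
                                f = curves$passive_fl),
    force_velocity = list(x = seq(-1.2, 1.2, length.out = n), f = curves$fv),
    tendon_force_strain = list(x = seq(-0.01, 0.08, length.out = n),
                               f = curves$tendon_fs)
  )
  out <- do.call(rbind, lapply(names(grid), function(nm) {
    data.frame(curve = nm, x = grid[[nm]]$x, y = grid[[nm]]$f(grid[[nm]]$x))
  }))
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(out)
}
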