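# Static optimization: resolve net joint moments into per-MTU activations
# plus reserve and residual actuator contributions, minimizing the summed
# squared activations at each time step independently.
#
# Formulation. At a timestep with pose q, velocity qd and net moments tau
# (per unlocked coordinate j):
#     sum_i a_i Fbar_i(q, qd) r_ij + reserve_j + residual moment_j = tau_j
# with Fbar_i the rigid-tendon, passive-free maximal force at the current
# kinematics. Reserves are eliminated exactly (reserve_j is the residual of
# the constraint), turning the problem into a strictly convex box-bounded
# quadratic program in (activations, residual forces):
#     min sum a_i^2 + sum_j w_j (reserve_j / R0)^2 + w_F |F_res / F0|^2
#         s.t. 0 <= a_i <= 1.
# The moment balance therefore holds to machine precision at every accepted
# timestep; optimality is certified by the KKT residual of the box QP.

#' Actuator set for static optimization
#'
#' One reserve actuator per unlocked coordinate plus two residual forces
#' (F_X, F_Y) applied at the model's center of mass. Reserve activation is
#' normalized by an "optimal moment" `reserve_optimal_moment` so that unit
#' reserve output (1 N mm by default) costs as much as full activation of a
#' muscle; the pelvic-tilt reserve and the residuals get a low cost weight
#' (they absorb the missing trunk/forelimb and are meant to be cheap).
#'
#' @param model a `hindlimb_model`.
#' @param reserve_weight cost weight of the limb-coordinate reserve
#'   actuators (default 1).
#' @param reserve_optimal_moment limb reserve normalization, N m (default
#'   1e-3 = 1 N mm).
#' @param residual_weight cost weight of the residual forces and of the
#'   pelvic-tilt reserve (default 1e-3).
#' @param pelvic_optimal_moment pelvic-tilt reserve normalization, N m
#'   (default 0.05, the scale of the pelvic-tilt moment, so this
#'   muscle-free coordinate's reserve is cheap and carries its whole
#'   moment).
#' @param residual_optimal_force residual normalization, N (default 0.01,
#'   ~5% of the peak GRF scale, so residuals absorb inconsistencies without
#'   substituting for the pelvic reserve).
#' @param residual_cap bound on |F_X|, |F_Y|, N.
#' @return list of class `actuator_set`.
#' @export
actuator_set <- function(model, reserve_weight = 1,
                         reserve_optimal_moment = 1e-3,
                         residual_weight = 1e-3,
                         pelvic_optimal_moment = 0.05,
                         residual_optimal_force = 0.01,
                         residual_cap = 1e3) {
  coords <- model$coordinates$name[!model$coordinates$locked]
  w <- stats::setNames(rep(reserve_weight, length(coords)), coords)
  R0 <- stats::setNames(rep(reserve_optimal_moment, length(coords)), coords)
  if ("pelvic_tilt" %in% coords) {
    w[["pelvic_tilt"]] <- residual_weight
    R0[["pelvic_tilt"]] <- pelvic_optimal_moment
  }
  structure(list(coordinates = coords, reserve_weight = w,
                 reserve_optimal_moment = R0,
                 residual_weight = residual_weight,
                 residual_optimal_force = residual_optimal_force,
                 residual_cap = residual_cap),
            class = "actuator_set")
}

#' Solve a box-constrained strictly convex quadratic program
#'
#' Minimizes `0.5 x' H x + g' x` subject to `lower <= x <= upper` by
#' projected-Newton active-set iteration. Used as the static-optimization
#' kernel; correctness is certified by the returned KKT residual (and, in
#' the test-suite, by grid-search and general-purpose-optimizer oracles).
#'
#' @param H symmetric positive-definite matrix.
#' @param g linear term.
#' @param lower,upper bounds (recycled).
#' @param tol KKT tolerance.
#' @param max_iter iteration guard.
#' @return list with `x`, `kkt` (max KKT violation), `iterations`,
#'   `converged`.
#' @export
solve_box_qp <- function(H, g, lower, upper, tol = 1e-9, max_iter = 500L) {
  n <- length(g)
  lower <- rep_len(lower, n); upper <- rep_len(upper, n)
  x <- pmin(pmax(numeric(n), lower), upper)
  # working sets: variables currently fixed at a bound
  ws_lo <- x <= lower
  ws_hi <- !ws_lo & x >= upper
  # multiplier scale: KKT tolerances relative to the problem's gradient size
  gscale <- max(abs(g), 1)
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    free <- !(ws_lo | ws_hi)
    moved <- FALSE
    if (any(free)) {
      rhs <- -(g[free] + H[free, !free, drop = FALSE] %*% x[!free])
      xf <- tryCatch(solve(H[free, free, drop = FALSE], rhs),
                     error = function(e) NULL)
      if (is.null(xf))
        xf <- drop(qr.solve(H[free, free, drop = FALSE], rhs,
                            tol = .Machine$double.eps))
      d <- drop(xf) - x[free]
      if (max(abs(d)) > 1e-14 * max(abs(x[free]) + 1)) {
        # longest feasible step toward the subspace minimizer
        alpha <- 1; block <- 0L; block_hi <- FALSE
        idx <- which(free)
        for (kk in seq_along(idx)) {
          i <- idx[kk]
          if (d[kk] > 0 && x[i] + d[kk] > upper[i]) {
            r <- (upper[i] - x[i]) / d[kk]
            if (r < alpha) { alpha <- r; block <- i; block_hi <- TRUE }
          } else if (d[kk] < 0 && x[i] + d[kk] < lower[i]) {
            r <- (lower[i] - x[i]) / d[kk]
            if (r < alpha) { alpha <- r; block <- i; block_hi <- FALSE }
          }
        }
        x[idx] <- x[idx] + alpha * d
        if (block > 0L) {
          if (block_hi) { x[block] <- upper[block]; ws_hi[block] <- TRUE }
          else { x[block] <- lower[block]; ws_lo[block] <- TRUE }
          moved <- TRUE
          next
        }
        moved <- TRUE
      }
    }
    # at the subspace minimizer: check bound multipliers, release the worst
    gv <- drop(H %*% x) + g
    viol_lo <- ws_lo & gv < -tol * gscale
    viol_hi <- ws_hi & gv > tol * gscale
    if (!any(viol_lo) && !any(viol_hi)) break
    score <- numeric(n)
    score[viol_lo] <- -gv[viol_lo]
    score[viol_hi] <- gv[viol_hi]
    rel <- which.max(score)
    ws_lo[rel] <- ws_hi[rel] <- FALSE
  }
  gv <- drop(H %*% x) + g
  r <- abs(gv)
  at_lo <- x <= lower + 1e-12
  at_hi <- x >= upper - 1e-12
  r[at_lo] <- pmax(-gv[at_lo], 0)
  r[at_hi] <- pmax(gv[at_hi], 0)
  kkt <- max(r)
  list(x = x, kkt = kkt, iterations = it,
       converged = kkt <= 10 * tol * gscale)
}

# Per-timestep ingredients: maximal muscle forces, moment-arm matrix over
# the actuator coordinates, residual-to-moment map (CoM Jacobian).
timestep_gains <- function(model, q, qd, actuators, curves, cache = NULL,
                           par = NULL) {
  q <- complete_pose(model, q)
  labels <- names(model$mtus)
  coords <- actuators$coordinates
  if (is.null(cache)) cache <- mtu_geometry_cache(model)
  if (is.null(par)) par <- mtu_param_matrix(model)
  R <- all_moment_arms(model, q, coords, cache)
  qd_s <- stats::setNames(rep(0, length(coordinate_order)), coordinate_order)
  qd_s[names(qd)] <- qd
  L <- all_mtu_lengths(model, q, cache)
  V <- -drop(R %*% qd_s[coords])
  Fbar <- rigid_forces_bulk(par, curves, rep(1, length(labels)), L, V)
  # residual forces act at the whole-model CoM but only through the
  # pelvis-ground coordinate set (pelvic_tilt; the base translations are
  # locked), so they cannot substitute for interior joint muscles
  bodies <- planar_bodies(model)
  fk <- fk_planar(model, q[sagittal_coords], bodies = bodies)
  mtot <- sum(bodies$mass)
  Jres <- matrix(0, 2, length(coords), dimnames = list(NULL, coords))
  if (mtot > 0 && "pelvic_tilt" %in% coords) {
    Jcom_tot <- Reduce(`+`, lapply(1:4, function(k)
      bodies$mass[k] * fk$Jcom[[k]])) / mtot
    colnames(Jcom_tot) <- sagittal_coords
    Jres[, "pelvic_tilt"] <- Jcom_tot[, "pelvic_tilt"]
  }
  G <- t(R[, coords, drop = FALSE]) * rep(Fbar, each = length(coords))
  list(G = G, Fbar = Fbar, Jres = Jres, labels = labels, coords = coords)
}

#' Static optimization at a single timestep
#'
#' @param model a `hindlimb_model`.
#' @param q named pose (radians).
#' @param qd named coordinate velocities (rad/s).
#' @param tau_net named net moments over the actuator coordinates, N m.
#' @param actuators an [actuator_set()].
#' @param curves a [default_muscle_curves()] object.
#' @param cache,par optional precomputed geometry cache / parameter matrix
#'   (internal speed-up for stride loops).
#' @return list with `activations` (named), `reserves` (N m, named),
#'   `residuals` (F_X, F_Y, N), `objective`, `kkt`, `converged`.
#' @export
solve_timestep <- function(model, q, qd, tau_net,
                           actuators = actuator_set(model),
                           curves = default_muscle_curves(),
                           cache = NULL, par = NULL) {
  gains <- timestep_gains(model, q, qd, actuators, curves, cache, par)
  coords <- gains$coords
  tau <- stats::setNames(rep(0, length(coords)), coords)
  tau[names(tau_net)] <- tau_net
  nm <- length(gains$labels)
  A <- cbind(gains$G, t(gains$Jres))   # coords x (muscles + 2 residuals)
  nv <- ncol(A)
  R0 <- actuators$reserve_optimal_moment[coords]
  W <- diag(actuators$reserve_weight[coords] / R0^2, length(coords))
  D <- diag(c(rep(1, nm),
              rep(actuators$residual_weight /
                    actuators$residual_optimal_force^2, 2)), nv)
  H <- 2 * (D + t(A) %*% W %*% A)
  g <- -2 * drop(t(A) %*% W %*% tau)
  lower <- c(rep(0, nm), rep(-actuators$residual_cap, 2))
  upper <- c(rep(1, nm), rep(actuators$residual_cap, 2))
  sol <- solve_box_qp(H, g, lower, upper)
  a <- stats::setNames(sol$x[seq_len(nm)], gains$labels)
  f_res <- stats::setNames(sol$x[nm + 1:2], c("F_X", "F_Y"))
  reserves <- stats::setNames(drop(tau - A %*% sol$x), coords)
  obj <- sum(a^2) +
    sum(actuators$reserve_weight[coords] * (reserves / R0)^2) +
    actuators$residual_weight *
      sum((f_res / actuators$residual_optimal_force)^2)
  list(activations = a, reserves = reserves, residuals = f_res,
       objective = obj, kkt = sol$kkt, converged = sol$converged,
       Fbar = stats::setNames(gains$Fbar, gains$labels),
       forces = stats::setNames(a * gains$Fbar, gains$labels))
}

#' Static optimization over a stride
#'
#' Solves every timestep independently (no energy transfer between steps).
#' Activations below 0.01 are reported as "not active".
#'
#' @param model a `hindlimb_model`.
#' @param stride a `stride_record` (gencoord series; velocities by central
#'   differences on the stride time base).
#' @param moments a `joint_moment_series` aligned with the stride samples
#'   (N m).
#' @param actuators an [actuator_set()].
#' @param curves muscle curves.
#' @param active_threshold reporting threshold (default 0.01).
#' @return object of class `activation_solution`: `time`, `activations`,
#'   `forces`, `reserves`, `residuals` matrices, `objective`, `kkt`,
#'   `active` logical matrix, `transition`.
#' @export
solve_stride <- function(model, stride, moments,
                         actuators = actuator_set(model),
                         curves = default_muscle_curves(),
                         active_threshold = 0.01) {
  time <- stride$normalized_time * stride$duration
  n <- length(time)
  coords <- actuators$coordinates
  qmat <- stride$joint_angles
  for (cc in setdiff(coords, names(qmat))) qmat[[cc]] <- 0
  dt <- time[2] - time[1]
  qd <- vapply(names(qmat), function(cc) series_deriv(qmat[[cc]], dt),
               numeric(n))
  labels <- names(model$mtus)
  acts <- matrix(0, n, length(labels), dimnames = list(NULL, labels))
  forces <- acts
  res <- matrix(0, n, length(coords), dimnames = list(NULL, coords))
  rsd <- matrix(0, n, 2, dimnames = list(NULL, c("F_X", "F_Y")))
  objective <- kkt <- numeric(n)
  cache <- mtu_geometry_cache(model)
  par <- mtu_param_matrix(model)
  for (i in seq_len(n)) {
    qi <- stats::setNames(as.numeric(qmat[i, ]), names(qmat))
    qdi <- stats::setNames(qd[i, ], names(qmat))
    taui <- stats::setNames(
      vapply(coords, function(cc)
        if (cc %in% names(moments)) moments[[cc]][i] else 0, numeric(1)),
      coords)
    s <- tryCatch(
      solve_timestep(model, qi, qdi, taui, actuators, curves, cache, par),
      error = function(e)
        stop_mousegait("mousegait_solver_failure",
                       sprintf("static optimization failed at timestep %d: %s",
                               i, conditionMessage(e))))
    acts[i, ] <- s$activations
    forces[i, ] <- s$forces
    res[i, ] <- s$reserves
    rsd[i, ] <- s$residuals
    objective[i] <- s$objective
    kkt[i] <- s$kkt
  }
  structure(list(time = time, activations = acts, forces = forces,
                 reserves = res, residuals = rsd, objective = objective,
                 kkt = kkt, active = acts >= active_threshold,
                 active_threshold = active_threshold,
                 transition = stride$transition),
            class = "activation_solution")
}

#' @export
print.activation_solution <- function(x, ...) {
  cat(sprintf("<activation_solution> %d timesteps, %d MTUs; max KKT residual %.2e\n",
              length(x$time), ncol(x$activations), max(x$kkt)))
  cat(sprintf("  MTUs ever active (a >= %.2g): %d\n", x$active_threshold,
              sum(colSums(x$active) > 0)))
  invisible(x)
}

#' Reserve and residual actuator diagnostics
#'
#' Time series of reserve moment / net moment per coordinate and residual
#' force / peak GRF, with excursions above the 5% reliability threshold
#' flagged.
#'
#' @param solution an `activation_solution`.
#' @param moments the `joint_moment_series` it was solved against (N m).
#' @param grf optional GRF data.frame (for the residual-to-peak-GRF ratio).
#' @param threshold flag level (default 0.05).
#' @return list with `reserve_share` (data.frame), `residual_ratio`,
#'   `flags` (per-coordinate logical: any excursion above threshold where
#'   the net moment is meaningful).
#' @export
actuator_diagnostics <- function(solution, moments, grf = NULL,
                                 threshold = 0.05) {
  coords <- colnames(solution$reserves)
  floor_m <- vapply(coords, function(cc)
    if (cc %in% names(moments)) 0.05 * max(abs(moments[[cc]]), 1e-12)
    else 1e-12, numeric(1))
  share <- vapply(seq_along(coords), function(j) {
    cc <- coords[j]
    tau <- if (cc %in% names(moments)) moments[[cc]] else
      rep(0, nrow(solution$reserves))
    # signed share: +1 means the reserve supplies the whole net moment
    solution$reserves[, j] /
      (ifelse(tau >= 0, 1, -1) * pmax(abs(tau), floor_m[j]))
  }, numeric(nrow(solution$reserves)))
  colnames(share) <- coords
  flags <- apply(abs(share) > threshold, 2, any)
  out <- list(reserve_share = as.data.frame(share), flags = flags)
  if (!is.null(grf)) {
    peak <- max(abs(grf$f_vertical), abs(grf$f_craniocaudal))
    rr <- abs(solution$residuals) / peak
    out$residual_ratio <- as.data.frame(rr)
    out$residual_flags <- apply(rr > threshold, 2, any)
  }
  out
}
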