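# Musculotendon mechanical work and functional classification.
#
# Sign convention: actuator power is positive when the MTU shortens under
# tension (concentric) and negative when it lengthens (eccentric); reserve
# power is moment times coordinate velocity. Positive/negative work are the
# areas under the positive/negative parts of the power curve; a stride is
# partitioned at the swing->stance transition.

#' Actuator power from force and MTU velocity
#'
#' `P(t) = F(t) * (-dL_mtu/dt)`, so shortening under tension is positive.
#'
#' @param force force series, N.
#' @param mtu_velocity MTU lengthening velocity series, m/s.
#' @return power series, W.
#' @export
actuator_power <- function(force, mtu_velocity) {
  if (length(force) != length(mtu_velocity))
    stop_mousegait("mousegait_input_error", "series must be aligned")
  force * (-mtu_velocity)
}

#' Positive, negative and net work from a power curve
#'
#' Trapezoidal areas under the positive and negative parts of the power
#' curve over a time window; `net = positive + negative`.
#'
#' @param time sample times, s.
#' @param power power series, W.
#' @param window `c(t0, t1)` inside the series (default: whole series).
#' @return list with `positive`, `negative`, `net`, in mJ.
#' @export
integrate_work <- function(time, power, window = range(time)) {
  if (window[1] < min(time) - 1e-12 || window[2] > max(time) + 1e-12)
    stop_mousegait("mousegait_input_error", "window outside series")
  keep <- time > window[1] + 1e-15 & time < window[2] - 1e-15
  # interpolate the window endpoints so adjacent windows tile the stride
  # exactly (trapezoids are linear-exact, so inserting the boundary node
  # preserves the whole-series integral)
  t <- c(window[1], time[keep], window[2])
  p <- c(stats::approx(time, power, xout = window[1])$y, power[keep],
         stats::approx(time, power, xout = window[2])$y)
  pos <- trapz(t, pmax(p, 0)) * 1000
  neg <- trapz(t, pmin(p, 0)) * 1000
  list(positive = pos, negative = neg, net = pos + neg)
}

#' Functional classification of an actuator
#'
#' Classifies an actuator from its stride work accounting and peak force:
#' `inactive` if it barely produces force; `motor` if net work is clearly
#' positive; `brake` if clearly negative; `spring` if net work is near zero
#' while substantial positive and negative work alternate; `strut`
#' otherwise (force without appreciable work). Thresholds are configurable;
#' the work threshold is a fraction of the actuator's largest phase-work
#' magnitude.
#'
#' @param work list/row with `positive_work_swing`, `negative_work_swing`,
#'   `positive_work_stance`, `negative_work_stance`, `net_work_stride` (mJ).
#' @param peak_force peak force over the stride, N.
#' @param f_max the actuator's maximal force, N (for the force floor).
#' @param w_thresh_frac work threshold as a fraction of the largest phase
#'   work magnitude (default 0.1).
#' @param force_floor_frac force floor as a fraction of `f_max`
#'   (default 0.01).
#' @param work_floor absolute work floor, mJ (default 1e-4): an actuator
#'   whose largest phase work is below it produces force without
#'   appreciable work and is a strut regardless of the relative
#'   thresholds.
#' @return one of `"motor"`, `"brake"`, `"strut"`, `"spring"`, `"inactive"`.
#' @export
classify_function <- function(work, peak_force, f_max,
                              w_thresh_frac = 0.1, force_floor_frac = 0.01,
                              work_floor = 1e-4) {
  if (peak_force < force_floor_frac * f_max) return("inactive")
  phase <- c(work$positive_work_swing, work$negative_work_swing,
             work$positive_work_stance, work$negative_work_stance)
  if (max(abs(phase)) < work_floor) return("strut")
  w_thresh <- w_thresh_frac * max(abs(phase))
  net <- work$net_work_stride
  pos <- work$positive_work_swing + work$positive_work_stance
  neg <- work$negative_work_swing + work$negative_work_stance
  if (net > w_thresh) return("motor")
  if (net < -w_thresh) return("brake")
  if (pos > w_thresh && abs(neg) > w_thresh) return("spring")
  "strut"
}

#' Reserve work as a percentage of a reference MTU's work
#'
#' @param reserve_net net work of the reserve actuator, mJ.
#' @param reference_net net work of the reference MTU, mJ (non-zero).
#' @return `100 * |reserve| / |reference|`.
#' @export
reserve_work_share <- function(reserve_net, reference_net) {
  if (reference_net == 0)
    stop_mousegait("mousegait_input_error",
                   "reference net work is zero; share undefined")
  100 * abs(reserve_net) / abs(reference_net)
}

#' Muscle analysis: MTU forces and powers from prescribed activations
#'
#' Re-evaluates each MTU along a kinematic trajectory with its activation
#' constrained to a prescribed series; tendon compliance is accounted for
#' (compliant mode of [mtu_force()], passive fiber force included). Powers
#' are computed at the MTU level (force times MTU shortening velocity).
#'
#' @param model a `hindlimb_model`.
#' @param time sample times, s.
#' @param q data.frame of gencoord series (radians).
#' @param activations matrix (time x MTU) of activations.
#' @param curves muscle curves.
#' @param compliant use the compliant-tendon force balance (default TRUE).
#' @return list with `time`, `length`, `velocity`, `force`, `power`
#'   matrices (time x MTU).
#' @export
muscle_analysis <- function(model, time, q, activations,
                            curves = default_muscle_curves(),
                            compliant = TRUE) {
  q <- as.data.frame(q)
  labels <- colnames(activations)
  n <- length(time)
  dt <- time[2] - time[1]
  cache <- mtu_geometry_cache(model)
  L <- matrix(0, n, length(cache$labels),
              dimnames = list(NULL, cache$labels))
  for (i in seq_len(n)) {
    qi <- complete_pose(model, stats::setNames(as.numeric(q[i, ]), names(q)))
    L[i, ] <- all_mtu_lengths(model, qi, cache)
  }
  L <- L[, labels, drop = FALSE]
  V <- apply(L, 2, series_deriv, dt = dt)
  F <- matrix(0, n, length(labels), dimnames = list(NULL, labels))
  mode <- if (compliant) "compliant" else "rigid"
  for (m in seq_along(labels)) {
    p <- model$mtus[[labels[m]]]$params
    for (i in seq_len(n)) {
      F[i, m] <- tryCatch(
        mtu_force(p, curves, min(max(activations[i, m], 0), 1),
                  L[i, m], V[i, m], mode = mode),
        mousegait_slack_tendon = function(e) 0)
    }
  }
  P <- F * (-V)
  list(time = time, length = L, velocity = V, force = F, power = P)
}

#' Per-actuator work summary and functional classification
#'
#' Splits each actuator's power curve at the swing->stance transition,
#' integrates positive/negative work per phase, and classifies the actuator.
#'
#' @param time sample times, s.
#' @param power matrix (time x actuator), W.
#' @param force matrix (time x actuator), N (peak force per actuator).
#' @param transition swing->stance transition as a fraction of the stride.
#' @param f_max named maximal forces, N, for the actuator columns (reserve
#'   actuators may pass their moment capacity; only the inactivity floor
#'   uses it).
#' @param w_thresh_frac,force_floor_frac see [classify_function()].
#' @return object of class `work_summary`: data.frame with one row per
#'   actuator (`positive_work_swing`, `negative_work_swing`,
#'   `positive_work_stance`, `negative_work_stance`, `net_work_stride` in
#'   mJ, `peak_force` in N, `functional_class`).
#' @export
work_summary <- function(time, power, force, transition, f_max,
                         w_thresh_frac = 0.1, force_floor_frac = 0.01) {
  labels <- colnames(power)
  t_split <- time[1] + transition * (time[length(time)] - time[1])
  rows <- lapply(labels, function(lb) {
    sw <- integrate_work(time, power[, lb], c(time[1], t_split))
    st <- integrate_work(time, power[, lb], c(t_split, time[length(time)]))
    w <- list(positive_work_swing = sw$positive,
              negative_work_swing = sw$negative,
              positive_work_stance = st$positive,
              negative_work_stance = st$negative,
              net_work_stride = sw$net + st$net)
    pk <- max(abs(force[, lb]))
    data.frame(actuator = lb, as.data.frame(w), peak_force = pk,
               functional_class = classify_function(
                 w, pk, f_max[[lb]], w_thresh_frac, force_floor_frac),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("work_summary", "data.frame")
  out
}

#' Work report for a solved stride
#'
#' Convenience wrapper: muscle analysis driven by a static-optimization
#' solution (compliant tendons), reserve-actuator powers from moment times
#' coordinate velocity, combined into a single work table.
#'
#' @param model a `hindlimb_model`.
#' @param stride the `stride_record`.
#' @param solution the `activation_solution` for that stride.
#' @param curves muscle curves.
#' @param compliant tendon compliance flag for the muscle analysis.
#' @return list with `summary` (a `work_summary` including reserve rows
#'   prefixed `reserve_`), `analysis` (the [muscle_analysis()] output) and
#'   `reserve_power`.
#' @export
work_report <- function(model, stride, solution,
                        curves = default_muscle_curves(),
                        compliant = TRUE) {
  time <- solution$time
  qtab <- stride$joint_angles
  ana <- muscle_analysis(model, time, qtab, solution$activations, curves,
                         compliant = compliant)
  dt <- time[2] - time[1]
  coords <- colnames(solution$reserves)
  qd <- vapply(coords, function(cc) {
    if (cc %in% names(qtab)) series_deriv(qtab[[cc]], dt)
    else rep(0, length(time))
  }, numeric(length(time)))
  reserve_power <- solution$reserves * qd
  colnames(reserve_power) <- paste0("reserve_", coords)
  power <- cbind(ana$power, reserve_power)
  force <- cbind(ana$force, abs(solution$reserves))
  colnames(force) <- colnames(power)
  fmax <- c(vapply(colnames(ana$power),
                   function(lb) model$mtus[[lb]]$params$f_max, numeric(1)),
            stats::setNames(rep(Inf, length(coords)),
                            paste0("reserve_", coords)))
  # a reserve's "f_max" is its own peak output, so any nonzero reserve
  # clears the inactivity floor
  for (cc in coords)
    fmax[[paste0("reserve_", cc)]] <-
      max(abs(solution$reserves[, cc])) + 1e-12
  summary <- work_summary(time, power, force, stride$transition, fmax)
  list(summary = summary, analysis = ana, reserve_power = reserve_power)
}
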