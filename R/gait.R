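# Gait processing: markers and force-plate records -> filtered joint-angle
# strides, stance-aligned ground reaction forces, and pooled stride means
# with 95% confidence intervals.
#
# Stride convention: a stride runs swing first, then stance; the swing->
# stance transition is stored as a fraction of stride time and the ground
# reaction force (GRF) is identically zero before it.

#' Marker trial container
#'
#' @param time sample times, s, strictly increasing.
#' @param markers named list of n x 2 matrices (columns x, y in m) for the
#'   labels `iliac_crest`, `hip`, `knee`, `ankle`, `mtp`.
#' @param frame_rate camera frame rate, Hz.
#' @return object of class `marker_trial`.
#' @export
marker_trial <- function(time, markers, frame_rate) {
  need <- c("iliac_crest", "hip", "knee", "ankle", "mtp")
  missing <- setdiff(need, names(markers))
  if (length(missing))
    stop_mousegait("mousegait_input_error",
                   paste("missing marker label(s):",
                         paste(missing, collapse = ", ")))
  if (any(diff(time) <= 0))
    stop_mousegait("mousegait_input_error", "time must be strictly increasing")
  for (m in need) {
    markers[[m]] <- as.matrix(markers[[m]])
    if (nrow(markers[[m]]) != length(time) || anyNA(markers[[m]]))
      stop_mousegait("mousegait_input_error",
                     paste("marker", m, "has missing frames"))
  }
  structure(list(time = time, markers = markers[need],
                 frame_rate = frame_rate),
            class = "marker_trial")
}

#' Force-plate trial container
#'
#' @param time sample times, s.
#' @param f_craniocaudal cranial(+)/caudal(-) GRF, N.
#' @param f_vertical dorsal-ventral (vertical, + up on the animal) GRF, N.
#' @param stance_window `c(t_on, t_off)` s, foot contact interval.
#' @return object of class `force_plate_trial`.
#' @export
force_plate_trial <- function(time, f_craniocaudal, f_vertical,
                              stance_window) {
  if (stance_window[1] >= stance_window[2])
    stop_mousegait("mousegait_input_error", "stance window must have t_on < t_off")
  structure(list(time = time, f_craniocaudal = f_craniocaudal,
                 f_vertical = f_vertical, stance_window = stance_window),
            class = "force_plate_trial")
}

#' Stride record container
#'
#' Time-normalized joint-angle and GRF trajectories for one stride.
#'
#' @param normalized_time stride fraction in `[0, 1]`.
#' @param joint_angles data.frame of gencoord series (radians), one column
#'   per coordinate.
#' @param grf data.frame with `f_craniocaudal` and `f_vertical` (N) on the
#'   stride time base (zero during swing).
#' @param transition swing->stance transition as a stride fraction.
#' @param duration stride duration, s.
#' @param speed forward speed, m/s.
#' @return object of class `stride_record`.
#' @export
stride_record <- function(normalized_time, joint_angles, grf, transition,
                          duration, speed = NA_real_) {
  if (transition <= 0 || transition >= 1)
    stop_mousegait("mousegait_input_error", "transition must be in (0, 1)")
  if (duration <= 0)
    stop_mousegait("mousegait_input_error", "duration must be positive")
  swing <- normalized_time < transition - 1e-12
  if (any(abs(grf$f_vertical[swing]) > 1e-9) ||
      any(abs(grf$f_craniocaudal[swing]) > 1e-9))
    stop_mousegait("mousegait_input_error", "GRF must be zero during swing")
  structure(list(normalized_time = normalized_time,
                 joint_angles = as.data.frame(joint_angles),
                 grf = as.data.frame(grf), transition = transition,
                 duration = duration, speed = speed),
            class = "stride_record")
}

#' @export
print.stride_record <- function(x, ...) {
  cat(sprintf("<stride_record> %d samples, duration %.4g s, duty factor %.3f, speed %.3g m/s\n",
              length(x$normalized_time), x$duration, duty_factor(x), x$speed))
  invisible(x)
}

#' Duty factor of a stride
#'
#' Stance duration divided by stride duration. For a swing-first stride with
#' transition fraction `f`, this is `1 - f`.
#'
#' @param stride a `stride_record`.
#' @return duty factor in `(0, 1)`.
#' @export
duty_factor <- function(stride) {
  1 - stride$transition
}

#' Ground reaction force as percent of body weight
#'
#' @param force force, N.
#' @param mass subject mass, kg.
#' @param g gravitational acceleration, m/s^2 (9.8 matches the published
#'   normalization).
#' @return `100 * |force| / (mass * g)`.
#' @export
grf_percent_bodyweight <- function(force, mass, g = 9.8) {
  stopifnot(mass > 0, g > 0)
  100 * abs(force) / (mass * g)
}

#' Joint angles from digitized markers
#'
#' Converts planar marker trajectories to generalized coordinates: pelvic
#' tilt is the angle of the iliac crest -> hip line above the horizontal;
#' hip, knee and ankle gencoords are inter-segment angles zeroed at the
#' fully extended pose, with the package sign conventions (positive hip
#' flexion, knee extension, ankle plantarflexion).
#'
#' @param trial a `marker_trial` (markers should be low-pass filtered first;
#'   see [lowpass_filter()]).
#' @return data.frame with `time`, `pelvic_tilt`, `hip_flexion`,
#'   `knee_extension`, `ankle_flexion` (radians).
#' @export
joint_angles_from_markers <- function(trial) {
  mk <- trial$markers
  seg_angle <- function(a, b, label) {
    d <- b - a
    r2 <- rowSums(d^2)
    if (any(r2 < 1e-16))
      stop_mousegait("mousegait_degenerate_frame",
                     paste("coincident markers in segment", label))
    atan2(d[, 2], d[, 1])
  }
  th_p <- seg_angle(mk$hip, mk$iliac_crest, "pelvis")
  th_t <- seg_angle(mk$hip, mk$knee, "thigh")
  th_s <- seg_angle(mk$knee, mk$ankle, "lower_leg")
  th_f <- seg_angle(mk$ankle, mk$mtp, "foot")
  data.frame(
    time = trial$time,
    pelvic_tilt = wrap_angle(th_p),
    hip_flexion = wrap_angle(th_t - th_p + pi),
    knee_extension = wrap_angle(th_s - th_t),
    ankle_flexion = wrap_angle(-(th_f - th_s))
  )
}

#' Marker positions from joint angles (forward kinematics)
#'
#' Inverse of [joint_angles_from_markers()]: places the five skin markers
#' from gencoord trajectories and a model's segment lengths.
#'
#' @param model a `hindlimb_model` (segment lengths).
#' @param angles data.frame with `pelvic_tilt`, `hip_flexion`,
#'   `knee_extension`, `ankle_flexion` (radians).
#' @param hip_path n x 2 matrix of world hip-joint positions (default: fixed
#'   at `c(0, 0.02)`).
#' @return named list of n x 2 marker matrices.
#' @export
markers_from_angles <- function(model, angles, hip_path = NULL) {
  n <- nrow(angles)
  len <- stats::setNames(model$segments$length, model$segments$name)
  if (is.null(hip_path))
    hip_path <- cbind(rep(0, n), rep(0.02, n))
  qp <- angles$pelvic_tilt; qh <- angles$hip_flexion
  qk <- angles$knee_extension; qa <- angles$ankle_flexion
  phi2 <- qp + qh - pi / 2
  phi3 <- phi2 + qk
  phi4 <- phi3 - qa
  dvec <- function(phi, L) cbind(L * sin(phi), -L * cos(phi))
  hip <- hip_path
  ic <- hip + cbind(len[["pelvis"]] * cos(qp), len[["pelvis"]] * sin(qp))
  knee <- hip + dvec(phi2, len[["thigh"]])
  ankle <- knee + dvec(phi3, len[["lower_leg"]])
  mtp <- ankle + dvec(phi4, len[["foot"]])
  list(iliac_crest = ic, hip = hip, knee = knee, ankle = ankle, mtp = mtp)
}

#' Build a stride record from marker and force-plate trials
#'
#' Full single-trial processing: low-pass filter the marker coordinates,
#' convert to gencoords, filter and resample the GRF channels onto the
#' stride time base (normalized to the whole stride, zero during swing).
#' The trial is assumed to span exactly one stride, swing first.
#'
#' @param markers a `marker_trial`.
#' @param forces a `force_plate_trial` whose stance window lies inside the
#'   marker trial's time span.
#' @param cutoff low-pass cutoff, Hz (default 20).
#' @param order Butterworth order per pass.
#' @param hip_adduction optional gencoord series (radians) on the marker
#'   time base (frontal-plane channel supplied separately).
#' @return a `stride_record`.
#' @export
process_trial <- function(markers, forces, cutoff = 20, order = 4,
                          hip_adduction = NULL) {
  fs <- markers$frame_rate
  filt <- markers
  filt$markers <- lapply(markers$markers, lowpass_filter, fs = fs,
                         cutoff = cutoff, order = order)
  ang <- joint_angles_from_markers(filt)
  t0 <- markers$time[1]
  duration <- markers$time[length(markers$time)] - t0
  phase <- (markers$time - t0) / duration
  transition <- (forces$stance_window[1] - t0) / duration
  fs_grf <- 1 / mean(diff(forces$time))
  fcc <- lowpass_filter(forces$f_craniocaudal, fs_grf, cutoff, order)
  fv <- lowpass_filter(forces$f_vertical, fs_grf, cutoff, order)
  in_stance <- markers$time >= forces$stance_window[1] &
    markers$time <= forces$stance_window[2]
  grf <- data.frame(f_craniocaudal = numeric(length(phase)),
                    f_vertical = numeric(length(phase)))
  if (any(in_stance)) {
    grf$f_craniocaudal[in_stance] <-
      stats::spline(forces$time, fcc, xout = markers$time[in_stance],
                    method = "fmm")$y
    grf$f_vertical[in_stance] <-
      stats::spline(forces$time, fv, xout = markers$time[in_stance],
                    method = "fmm")$y
  }
  hipx <- filt$markers$hip[, 1]
  speed <- (hipx[length(hipx)] - hipx[1]) / duration
  ja <- ang[, c("pelvic_tilt", "hip_flexion", "knee_extension",
                "ankle_flexion")]
  if (!is.null(hip_adduction)) ja$hip_adduction <- hip_adduction
  stride_record(phase, ja, grf, transition, duration, speed)
}

#' Resample strides to a common base and pool them
#'
#' Each channel (joint angles and GRF) of each stride is resampled to
#' `n_points` by cubic-spline interpolation on normalized stride time; the
#' pooled mean and pointwise normal-theory 95% confidence half-widths
#' (`1.96 * SE`) are returned.
#'
#' @param strides list of `stride_record`s sharing channel names.
#' @param n_points samples of the common base (>= 4; default 101).
#' @return object of class `pooled_stride`: `normalized_time`, `mean` and
#'   `ci95` data.frames, `n_trials`.
#' @export
normalize_and_pool <- function(strides, n_points = 101) {
  if (n_points < 4)
    stop_mousegait("mousegait_input_error", "n_points must be >= 4")
  if (!length(strides))
    stop_mousegait("mousegait_input_error", "need at least one stride")
  grid <- seq(0, 1, length.out = n_points)
  channels <- c(names(strides[[1]]$joint_angles), names(strides[[1]]$grf))
  resampled <- lapply(strides, function(s) {
    tab <- cbind(s$joint_angles, s$grf)
    vapply(channels, function(ch) {
      stats::spline(s$normalized_time, tab[[ch]], xout = grid,
                    method = "fmm")$y
    }, numeric(n_points))
  })
  arr <- simplify2array(resampled)   # n_points x channels x trials
  if (length(dim(arr)) == 2) arr <- array(arr, c(dim(arr), 1))
  mu <- apply(arr, c(1, 2), mean)
  n <- length(strides)
  ci <- if (n > 1) 1.96 * apply(arr, c(1, 2), stats::sd) / sqrt(n)
        else matrix(0, n_points, length(channels))
  colnames(mu) <- colnames(ci) <- channels
  structure(list(normalized_time = grid, mean = as.data.frame(mu),
                 ci95 = as.data.frame(ci), n_trials = n),
            class = "pooled_stride")
}

#' @export
print.pooled_stride <- function(x, ...) {
  cat(sprintf("<pooled_stride> %d trials, %d points, channels: %s\n",
              x$n_trials, length(x$normalized_time),
              paste(names(x$mean), collapse = ", ")))
  invisible(x)
}
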