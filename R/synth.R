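# Synthetic trotting-gait generator.
#
# Emulates the statistical structure of published mouse trotting data so
# the whole pipeline is testable without laboratory recordings: a ~0.128 s
# stride with duty factor 0.4375 (swing first), smooth periodic joint-angle
# excursions, a single-peaked vertical GRF reaching ~120% body weight at
# 55.1% of stance, a biphasic fore-aft GRF (braking then propulsion), and
# optional marker digitization noise. Identical (params, seed) give
# identical output.

default_joint_waves <- function() {
  # degrees; q(phase) = mean + a1 cos(2 pi (phase - p1))
  #                          + a2 cos(4 pi (phase - p2)), periodic in the
  # stride so value and velocity are continuous across the wrap.
  data.frame(
    coordinate = c("pelvic_tilt", "hip_flexion", "hip_adduction",
                   "knee_extension", "ankle_flexion"),
    mean_deg = c(15, 35, 5, -50, 0),
    amp1_deg = c(3, 20, 3, 15, 20),
    phase1 = c(0.6, 0.28, 0.3, 0.8, 0.9),
    amp2_deg = c(1, 4, 1, 5, 6),
    phase2 = c(0.1, 0.1, 0.1, 0.15, 0.3),
    stringsAsFactors = FALSE
  )
}

#' Synthetic gait parameters
#'
#' Defaults are the published landmark values for mouse trotting: stride
#' duration 0.128 s with the swing->stance transition at 0.072 s (duty
#' factor 0.4375), speed 0.59 m/s, subject mass 18.7 g, vertical GRF peak
#' 120% body weight at 55.1% of stance, braking/propulsive fore-aft peaks
#' 10.9%/8.19% body weight (g = 9.8 in the body-weight normalization, as
#' published). Joint-wave amplitudes are model choices spanning
#' gait-plausible ranges (see the package vignette).
#'
#' @param stride_duration s.
#' @param duty_factor stance fraction of the stride.
#' @param speed forward speed, m/s.
#' @param subject_mass kg.
#' @param g m/s^2 used in body-weight normalization.
#' @param grf_peak_bw vertical GRF peak, fraction of body weight.
#' @param grf_peak_at vertical peak location, fraction of stance.
#' @param braking_peak_bw,propulsion_peak_bw fore-aft lobe peaks, fraction
#'   of body weight.
#' @param joint_waves data.frame of per-coordinate Fourier descriptors
#'   (degrees), see `default_joint_waves`.
#' @param knee_stance_excursion_deg optional target for the knee gencoord's
#'   stance-phase excursion (degrees); the knee wave is rescaled to hit it
#'   exactly (the published stance knee excursion is 18 degrees).
#' @param marker_noise_sd marker digitization noise SD, m.
#' @param frame_rate marker sampling rate, Hz.
#' @param seed RNG seed (determinism contract).
#' @return object of class `gait_params`.
#' @export
gait_params <- function(stride_duration = 0.128, duty_factor = 0.4375,
                        speed = 0.59, subject_mass = 0.0187, g = 9.8,
                        grf_peak_bw = 1.20, grf_peak_at = 0.551,
                        braking_peak_bw = 0.109,
                        propulsion_peak_bw = 0.0819,
                        joint_waves = default_joint_waves(),
                        knee_stance_excursion_deg = NULL,
                        marker_noise_sd = 0, frame_rate = 250,
                        seed = 1L) {
  stopifnot(stride_duration > 0, duty_factor > 0, duty_factor < 1,
            subject_mass > 0, g > 0, grf_peak_bw >= 0,
            grf_peak_at > 0, grf_peak_at < 1,
            braking_peak_bw >= 0, propulsion_peak_bw >= 0,
            marker_noise_sd >= 0, frame_rate > 0)
  structure(list(stride_duration = stride_duration,
                 duty_factor = duty_factor, speed = speed,
                 subject_mass = subject_mass, g = g,
                 grf_peak_bw = grf_peak_bw, grf_peak_at = grf_peak_at,
                 braking_peak_bw = braking_peak_bw,
                 propulsion_peak_bw = propulsion_peak_bw,
                 joint_waves = joint_waves,
                 knee_stance_excursion_deg = knee_stance_excursion_deg,
                 marker_noise_sd = marker_noise_sd,
                 frame_rate = frame_rate, seed = as.integer(seed)),
            class = "gait_params")
}

synth_time <- function(p, n = NULL) {
  if (is.null(n)) n <- max(round(p$stride_duration * p$frame_rate), 8) + 1
  seq(0, p$stride_duration, length.out = n)
}

#' Generate synthetic joint-angle series
#'
#' Smooth periodic gencoord trajectories (two-harmonic truncated Fourier
#' series per coordinate), continuous in value and velocity across the
#' stride. Amplitudes that would push a coordinate outside its default
#' range are clipped with a warning.
#'
#' @param p a [gait_params()] object.
#' @param n number of samples (default from `frame_rate`).
#' @return data.frame with `time` (s) and one radian series per coordinate.
#' @export
generate_angles <- function(p, n = NULL) {
  time <- synth_time(p, n)
  phase <- time / p$stride_duration
  jw <- p$joint_waves
  out <- data.frame(time = time)
  for (i in seq_len(nrow(jw))) {
    q <- jw$mean_deg[i] +
      jw$amp1_deg[i] * cos(2 * pi * (phase - jw$phase1[i])) +
      jw$amp2_deg[i] * cos(4 * pi * (phase - jw$phase2[i]))
    out[[jw$coordinate[i]]] <- deg2rad(q)
  }
  if (!is.null(p$knee_stance_excursion_deg)) {
    stance <- phase >= 1 - p$duty_factor - 1e-12
    k <- out$knee_extension
    exc <- rad2deg(max(k[stance]) - min(k[stance]))
    if (exc > 0) {
      scale <- p$knee_stance_excursion_deg / exc
      out$knee_extension <- mean(k) + (k - mean(k)) * scale
    }
  }
  co <- default_coordinates()
  for (cc in co$name) {
    lo <- co$lower[co$name == cc]; hi <- co$upper[co$name == cc]
    if (any(out[[cc]] < lo | out[[cc]] > hi)) {
      warning("clipping ", cc, " to its coordinate range")
      out[[cc]] <- pmin(pmax(out[[cc]], lo), hi)
    }
  }
  out
}

#' Generate a synthetic ground reaction force trial
#'
#' Vertical channel: a smooth single-peaked beta-shaped curve over stance,
#' zero at the stance edges, peaking at `grf_peak_bw * m * g` exactly at
#' `grf_peak_at` of stance. Fore-aft channel: braking (caudal, negative)
#' half-sine over the first half of stance, propulsive half-sine over the
#' second, with the stated body-weight peak fractions. Zero during swing.
#'
#' @param p a [gait_params()] object.
#' @param n number of samples over the whole stride.
#' @return a `force_plate_trial` spanning the whole stride.
#' @export
generate_grf <- function(p, n = NULL) {
  time <- synth_time(p, n)
  t_on <- (1 - p$duty_factor) * p$stride_duration
  t_off <- p$stride_duration
  s <- (time - t_on) / (t_off - t_on)
  in_st <- s >= 0 & s <= 1
  bw <- p$subject_mass * p$g
  # beta bump with mode exactly at grf_peak_at
  k <- 3
  al <- 1 + k * p$grf_peak_at; be <- 1 + k * (1 - p$grf_peak_at)
  bump <- function(x) ifelse(x > 0 & x < 1, x^(al - 1) * (1 - x)^(be - 1), 0)
  fz <- numeric(length(time))
  fz[in_st] <- p$grf_peak_bw * bw * bump(s[in_st]) / bump(p$grf_peak_at)
  fx <- numeric(length(time))
  first <- in_st & s <= 0.5
  second <- in_st & s > 0.5
  fx[first] <- -p$braking_peak_bw * bw * sin(2 * pi * s[first])
  fx[second] <- p$propulsion_peak_bw * bw * sin(2 * pi * (s[second] - 0.5))
  force_plate_trial(time, fx, fz, c(t_on, t_off))
}

#' Generate a synthetic marker trial from joint angles
#'
#' Forward-kinematics placement of the five skin markers from generated
#' gencoords, the hip translating at the stride speed, plus i.i.d. Gaussian
#' digitization noise. With zero noise the trial round-trips exactly
#' through [joint_angles_from_markers()].
#'
#' @param p a [gait_params()] object (speed, noise SD, seed).
#' @param angles output of [generate_angles()].
#' @param model a `hindlimb_model` (segment lengths).
#' @return a `marker_trial`.
#' @export
generate_markers <- function(p, angles, model) {
  n <- nrow(angles)
  hip_path <- cbind(p$speed * angles$time, rep(0.02, n))
  mk <- markers_from_angles(model, angles, hip_path)
  if (p$marker_noise_sd > 0) {
    mk <- with_seed(p$seed, lapply(mk, function(m)
      m + matrix(stats::rnorm(length(m), sd = p$marker_noise_sd),
                 nrow(m), ncol(m))))
  }
  marker_trial(angles$time, mk, p$frame_rate)
}

#' Generate one mutually consistent synthetic trial
#'
#' Angles, markers and GRF generated from the same parameters: markers are
#' forward kinematics of the angles, the GRF window is the stance phase,
#' and the returned `stride` holds the generating (ground-truth) series.
#'
#' @param p a [gait_params()] object.
#' @param model a `hindlimb_model`.
#' @param n samples per stride.
#' @return list of class `synthetic_trial` with `stride` (ground-truth
#'   `stride_record`), `markers` (`marker_trial`), `forces`
#'   (`force_plate_trial`).
#' @export
generate_trial <- function(p, model = build_default_model(), n = NULL) {
  angles <- generate_angles(p, n)
  forces <- generate_grf(p, n)
  markers <- generate_markers(p, angles, model)
  phase <- angles$time / p$stride_duration
  grf <- data.frame(f_craniocaudal = forces$f_craniocaudal,
                    f_vertical = forces$f_vertical)
  ja <- angles[, setdiff(names(angles), "time")]
  stride <- stride_record(phase, ja, grf,
                          transition = 1 - p$duty_factor,
                          duration = p$stride_duration, speed = p$speed)
  structure(list(stride = stride, markers = markers, forces = forces,
                 params = p), class = "synthetic_trial")
}

#' Generate a set of synthetic trials with inter-trial variability
#'
#' Trials are drawn with multiplicative Gaussian variability on the joint
#' wave amplitudes and stride duration (per-trial seeds derived from the
#' set seed), mirroring the pooled experimental design (44 trials from 5
#' mice by default).
#'
#' @param p baseline [gait_params()].
#' @param n_trials number of trials (default 44).
#' @param amp_cv coefficient of variation of wave amplitudes (default 0.05).
#' @param duration_cv coefficient of variation of stride duration
#'   (default 0.03).
#' @param model a `hindlimb_model`.
#' @param n samples per stride.
#' @return list of `synthetic_trial`s.
#' @export
generate_trial_set <- function(p, n_trials = 44, amp_cv = 0.05,
                               duration_cv = 0.03,
                               model = build_default_model(), n = NULL) {
  stopifnot(n_trials >= 1)
  draws <- with_seed(p$seed, {
    lapply(seq_len(n_trials), function(i)
      list(amp = stats::rnorm(1, 1, amp_cv),
           dur = stats::rnorm(1, 1, duration_cv),
           sub_seed = sample.int(.Machine$integer.max, 1)))
  })
  lapply(seq_len(n_trials), function(i) {
    d <- draws[[i]]
    pi <- p
    pi$joint_waves$amp1_deg <- p$joint_waves$amp1_deg * max(d$amp, 0.1)
    pi$joint_waves$amp2_deg <- p$joint_waves$amp2_deg * max(d$amp, 0.1)
    pi$stride_duration <- p$stride_duration * max(d$dur, 0.5)
    pi$seed <- d$sub_seed
    generate_trial(pi, model, n)
  })
}
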