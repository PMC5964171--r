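# Musculoskeletal model of the mouse hindlimb and pelvis.
#
# Kinematic conventions (package-wide):
#   * world frame: +x cranial (direction of travel), +y dorsal (up),
#     +z medio-lateral; the sagittal plane is x-y.
#   * generalized coordinates (gencoords) are zero at the fully extended
#     reference pose, in which the limb lies straight and caudal, in line
#     with a horizontal pelvis.
#   * positive senses: pelvic tilt = cranial end up; hip flexion = thigh
#     swings cranially; knee extension (gait values are negative = flexed);
#     ankle flexion positive = plantarflexion (the published figure
#     convention; see vignette for the source's internal inconsistency);
#     hip adduction = limb toward the midline.
#   * angles are radians internally, degrees at user interfaces.

coordinate_order <- c("pelvic_tilt", "hip_flexion", "hip_adduction",
                      "knee_extension", "ankle_flexion")
sagittal_coords <- c("pelvic_tilt", "hip_flexion", "knee_extension",
                     "ankle_flexion")

default_coordinates <- function() {
  data.frame(
    name = coordinate_order,
    positive_sense = c("cranial end of pelvis up", "thigh swings cranially",
                       "limb toward midline", "knee straightens",
                       "plantarflexion"),
    lower = deg2rad(c(-20, -20, -40, -130, -70)),
    upper = deg2rad(c(60, 110, 40, 20, 80)),
    locked = FALSE,
    stringsAsFactors = FALSE
  )
}

# Functional-group routing used by the procedural path generator: the joint
# crossed, the coordinate whose moment the group primarily produces, the
# required moment-arm sign about that coordinate, and the perpendicular
# offset (m) of the synthetic path from the joint center (which is the
# moment-arm magnitude near the calibration pose). Groups acting about
# unmodeled degrees of freedom (hip long-axis rotators, ankle everters) get
# small arms on the anatomically adjacent side.
group_routing <- function() {
  data.frame(
    group = c("hip_rotator", "hip_adductor", "hip_flexor", "hip_extensor",
              "knee_extensor", "knee_flexor", "ankle_dorsiflexor",
              "ankle_plantarflexor", "ankle_everter"),
    joint = c("hip", "hip", "hip", "hip", "knee", "knee",
              "ankle", "ankle", "ankle"),
    coordinate = c("hip_flexion", "hip_adduction", "hip_flexion",
                   "hip_flexion", "knee_extension", "knee_extension",
                   "ankle_flexion", "ankle_flexion", "ankle_flexion"),
    sign = c(-1, 1, 1, -1, 1, -1, -1, 1, 1),
    offset = c(0.0005, 0.0015, 0.002, 0.002, 0.0015, 0.0015,
               0.0015, 0.0015, 0.0005),
    stringsAsFactors = FALSE
  )
}

joint_segments <- function(joint) {
  switch(joint,
    hip = c("pelvis", "thigh"),
    knee = c("thigh", "lower_leg"),
    ankle = c("lower_leg", "foot"),
    stop_mousegait("mousegait_input_error", paste("unknown joint:", joint))
  )
}

#' Segment frames at a pose
#'
#' Homogeneous 4x4 transforms (segment frame to world) for every segment of
#' the model at pose `q`. Segment frames have their origin at the proximal
#' joint with -y toward the distal joint; the torso is rigidly attached to
#' the pelvis and shares its frame.
#'
#' @param model a `hindlimb_model`.
#' @param q named pose vector (radians) over the model coordinates; missing
#'   coordinates default to 0.
#' @param base world position of the hip joint (length-2 or -3).
#' @return named list of 4x4 transforms (`pelvis`, `torso`, `thigh`,
#'   `lower_leg`, `foot`).
#' @export
segment_transforms <- function(model, q, base = c(0, 0, 0)) {
  q <- complete_pose(model, q)
  if (length(base) == 2) base <- c(base, 0)
  len <- stats::setNames(model$segments$length, model$segments$name)
  T_pelvis <- htransform(rot_z(q[["pelvic_tilt"]]), base)
  T_thigh <- T_pelvis %*%
    htransform(rot_x(q[["hip_adduction"]]) %*%
               rot_z(q[["hip_flexion"]] - pi / 2))
  T_shank <- T_thigh %*% htransform(t = c(0, -len[["thigh"]], 0)) %*%
    htransform(rot_z(q[["knee_extension"]]))
  T_foot <- T_shank %*% htransform(t = c(0, -len[["lower_leg"]], 0)) %*%
    htransform(rot_z(-q[["ankle_flexion"]]))
  list(pelvis = T_pelvis, torso = T_pelvis, thigh = T_thigh,
       lower_leg = T_shank, foot = T_foot)
}

complete_pose <- function(model, q) {
  full <- stats::setNames(numeric(length(coordinate_order)), coordinate_order)
  if (!is.null(names(q))) {
    bad <- setdiff(names(q), coordinate_order)
    if (length(bad))
      stop_mousegait("mousegait_input_error",
                     paste("unknown coordinate(s):", paste(bad, collapse = ", ")))
    full[names(q)] <- q
  } else {
    if (length(q) != length(coordinate_order))
      stop_mousegait("mousegait_input_error",
                     "unnamed pose must have one value per coordinate")
    full[] <- q
  }
  full
}

check_pose_range <- function(model, q) {
  q <- complete_pose(model, q)
  co <- model$coordinates
  lo <- stats::setNames(co$lower, co$name)[names(q)]
  hi <- stats::setNames(co$upper, co$name)[names(q)]
  bad <- which(q < lo - 1e-12 | q > hi + 1e-12)
  if (length(bad))
    stop_mousegait("mousegait_range_violation",
                   paste0("pose outside coordinate range: ",
                          paste(names(q)[bad], collapse = ", ")))
  invisible(q)
}

#' Reference (fully extended) pose
#'
#' @param model a `hindlimb_model`.
#' @return named zero vector over the model coordinates.
#' @export
reference_pose <- function(model) {
  stats::setNames(numeric(length(coordinate_order)), coordinate_order)
}

# Mid-gait pose at which moment-arm signs are calibrated; the reference pose
# is degenerate for hip adduction (thigh along the adduction axis).
calibration_pose <- function(model) {
  q <- reference_pose(model)
  q["hip_flexion"] <- deg2rad(45)
  q["knee_extension"] <- deg2rad(-45)
  q
}

#' Build the default mouse hindlimb model
#'
#' Assembles the hindlimb musculoskeletal model from the published parameter
#' tables: every MTU row of [mtu_parameter_table()] (force-generating
#' constants exactly as printed) and every segment of
#' [segment_inertia_table()]. Muscle-path geometry is not printed in the
#' source and is generated procedurally: each MTU gets a three-point pulley
#' via path about the joint its functional group crosses, calibrated so that
#'
#' * its path length at the fully extended reference pose equals
#'   `l_ts + l_opt * cos(pennation0)` exactly, and
#' * the sign of its moment arm about its primary coordinate matches its
#'   functional group (flexors cranial/positive, extensors caudal/negative,
#'   plantarflexors caudal to the ankle axis, ...), verified numerically at
#'   a mid-gait calibration pose.
#'
#' @param v_max maximal contractile velocity passed to
#'   [mtu_parameter_table()].
#' @param gravity gravitational acceleration magnitude, m s^-2 (downward).
#' @return an object of class `hindlimb_model`: list with `segments`,
#'   `coordinates`, `mtus` (named by abbreviation), `gravity`, `foot_cop`
#'   (center-of-pressure point in the foot frame).
#' @export
build_default_model <- function(v_max = 10, gravity = 9.81) {
  params <- mtu_parameter_table(v_max = v_max)
  segments <- segment_inertia_table()
  model <- structure(
    list(
      segments = segments,
      coordinates = default_coordinates(),
      mtus = list(),
      gravity = gravity,
      # CoP fixed at the mid-point of the distal end of the metatarsals:
      # metatarsal distal end 5 mm along the foot, phalanges ~4 mm beyond.
      foot_cop = c(0, -0.005, 0)
    ),
    class = "hindlimb_model"
  )
  routing <- group_routing()
  Tref <- segment_transforms(model, reference_pose(model))
  qcal <- calibration_pose(model)
  len <- stats::setNames(segments$length, segments$name)
  hip_w <- c(0, 0, 0)
  knee_w <- c(-len[["thigh"]], 0, 0)
  ankle_w <- c(-len[["thigh"]] - len[["lower_leg"]], 0, 0)
  mtus <- vector("list", nrow(params))
  names(mtus) <- params$abbreviation
  for (i in seq_len(nrow(params))) {
    p <- as.list(params[i, ])
    r <- routing[routing$group == p$group, ]
    segs <- joint_segments(r$joint)
    jw <- switch(r$joint, hip = hip_w, knee = knee_w, ankle = ankle_w)
    L0 <- p$l_ts + p$l_opt * cos(deg2rad(p$pennation0))
    nhat <- if (r$coordinate == "hip_adduction") c(0, 0, 1) else c(0, 1, 0)
    build_path <- function(side)
      make_pulley_path(jw, L0, side * nhat * r$offset, segs, Tref)
    mtus[[i]] <- calibrate_path_sign(model, p, build_path, qcal,
                                     r$coordinate, r$sign)
  }
  model$mtus <- mtus
  model
}

# Three-point pulley path about a joint: origin on the proximal segment,
# a pulley point fixed to the proximal segment at the joint's perpendicular
# offset, and an insertion on the distal segment, all laid out along the
# reference limb axis (+x proximal, -x distal) at the same perpendicular
# offset. The reference-pose length is exactly L0 and the moment-arm sign
# about the joint is stable across the gait range of joint rotations
# (the pulley leg pivots instead of the whole chord sweeping through the
# joint center). Each point is expressed in its owning segment's frame via
# the reference-pose transforms.
make_pulley_path <- function(joint_w, L0, offset_w, segs, Tref) {
  A_w <- joint_w + c(L0 / 2, 0, 0) + offset_w
  P_w <- joint_w + offset_w
  B_w <- joint_w + c(-L0 / 2, 0, 0) + offset_w
  to_seg <- function(p, seg) {
    out <- drop(happly(solve(Tref[[seg]]), p))
    out[abs(out) < 1e-12] <- 0  # zap frame-conversion noise (sub-picometer)
    out
  }
  A_l <- to_seg(A_w, segs[1])
  P_l <- to_seg(P_w, segs[1])
  B_l <- to_seg(B_w, segs[2])
  via <- data.frame(segment = c(segs[1], segs[1], segs[2]),
                    x = c(A_l[1], P_l[1], B_l[1]),
                    y = c(A_l[2], P_l[2], B_l[2]),
                    z = c(A_l[3], P_l[3], B_l[3]),
                    stringsAsFactors = FALSE)
  spanned <- if (segs[1] == "pelvis") c("hip_flexion", "hip_adduction")
             else if (segs[1] == "thigh") "knee_extension" else "ankle_flexion"
  list(via = via, spanned = spanned)
}

# Numerically verify the moment-arm sign about the primary coordinate at
# the calibration pose; mirror the path to the joint's other side if wrong.
calibrate_path_sign <- function(model, params, build_path, qcal,
                                coordinate, sign_target) {
  for (side in c(1, -1)) {
    mtu <- list(params = params, path = build_path(side))
    model$mtus <- list(X = mtu)
    r <- moment_arm(model, qcal, "X", coordinate)
    if (abs(r) < 1e-9)
      stop_mousegait("mousegait_model_error",
                     "degenerate moment arm during path calibration")
    if (sign(r) == sign_target) {
      mtu$path$primary <- coordinate
      mtu$path$primary_sign <- sign_target
      return(mtu)
    }
  }
  stop_mousegait("mousegait_model_error", "path sign calibration failed")
}

#' @export
print.hindlimb_model <- function(x, ...) {
  cat("<hindlimb_model>\n")
  cat(sprintf("  %d segments, %d coordinates, %d MTUs, gravity %.2f m/s^2\n",
              nrow(x$segments), nrow(x$coordinates), length(x$mtus),
              x$gravity))
  invisible(x)
}

get_mtu <- function(model, mtu) {
  m <- model$mtus[[mtu]]
  if (is.null(m))
    stop_mousegait("mousegait_input_error", paste("unknown MTU label:", mtu))
  m
}

#' Musculotendon path length at a pose
#'
#' Sum of Euclidean distances between consecutive via points expressed in the
#' world frame at pose `q`.
#'
#' @param model a `hindlimb_model`.
#' @param q named pose vector, radians.
#' @param mtu MTU abbreviation (e.g. `"RF"`).
#' @param check_range signal a range violation if `q` is outside the
#'   coordinate ranges (default TRUE; internal finite-difference probes
#'   disable it).
#' @return path length, m.
#' @export
mtu_length <- function(model, q, mtu, check_range = TRUE) {
  m <- get_mtu(model, mtu)
  q <- complete_pose(model, q)
  if (check_range) check_pose_range(model, q)
  Ts <- segment_transforms(model, q)
  via <- m$path$via
  pts <- matrix(0, 3, nrow(via))
  for (i in seq_len(nrow(via))) {
    pts[, i] <- drop(happly(Ts[[via$segment[i]]],
                            c(via$x[i], via$y[i], via$z[i])))
  }
  L <- sum(sqrt(rowSums(diff(t(pts))^2)))
  if (L <= 0)
    stop_mousegait("mousegait_model_error", "non-positive MTU length")
  L
}

#' Moment arm of an MTU about a coordinate (tendon-excursion method)
#'
#' `r = -d(mtu_length)/d(coordinate)` by central difference, so a positive
#' moment arm means tensile MTU force produces a positive generalized moment
#' about `coord`.
#'
#' @inheritParams mtu_length
#' @param coord coordinate label.
#' @param step finite-difference step, radians.
#' @return moment arm, m.
#' @export
moment_arm <- function(model, q, mtu, coord, step = 1e-5) {
  q <- complete_pose(model, q)
  check_pose_range(model, q)
  if (!coord %in% coordinate_order)
    stop_mousegait("mousegait_input_error", paste("unknown coordinate:", coord))
  qp <- qm <- q
  qp[coord] <- qp[coord] + step
  qm[coord] <- qm[coord] - step
  -(mtu_length(model, qp, mtu, check_range = FALSE) -
      mtu_length(model, qm, mtu, check_range = FALSE)) / (2 * step)
}

#' Published model scale factors
#'
#' The segment scale factors used to match the model to the experimental
#' subject (torso 0.936, pelvis 0.936, thigh 1.065, lower leg 0.926,
#' pedal 1.244).
#'
#' @return named numeric vector over segments.
#' @export
paper_scale_factors <- function() {
  c(torso = 0.936, pelvis = 0.936, thigh = 1.065, lower_leg = 0.926,
    foot = 1.244)
}

#' Scale the model by per-segment linear factors
#'
#' Segment lengths, center-of-mass offsets and via-point coordinates are
#' multiplied by the owning segment's factor; masses scale with factor^3 and
#' inertias with factor^5 (geometric similarity). Each MTU's optimal fiber
#' and tendon slack lengths are rescaled by the ratio of its reference-pose
#' path length after/before scaling, which preserves the reference-pose
#' normalized fiber length and slack margin.
#'
#' @param model a `hindlimb_model`.
#' @param factors named per-segment scalars; `"pedal"` is accepted as an
#'   alias for `"foot"` and `"lower leg"` for `"lower_leg"`. Unnamed
#'   segments keep factor 1.
#' @param subject_mass optional total body mass (kg); if given, all segment
#'   masses are renormalized after scaling so they sum to it.
#' @return the scaled `hindlimb_model`.
#' @export
scale_model <- function(model, factors, subject_mass = NULL) {
  names(factors) <- sub("^pedal$", "foot", names(factors))
  names(factors) <- gsub(" ", "_", names(factors))
  bad <- setdiff(names(factors), model$segments$name)
  if (length(bad))
    stop_mousegait("mousegait_input_error",
                   paste("unknown segment(s):", paste(bad, collapse = ", ")))
  if (any(factors <= 0))
    stop_mousegait("mousegait_input_error", "scale factors must be positive")
  f <- stats::setNames(rep(1, nrow(model$segments)), model$segments$name)
  f[names(factors)] <- factors
  qref <- reference_pose(model)
  L_old <- vapply(names(model$mtus),
                  function(a) mtu_length(model, qref, a), numeric(1))
  sc <- model$segments
  fx <- f[sc$name]
  for (col in c("com_x", "com_y", "com_z", "chain_x", "chain_y", "length"))
    sc[[col]] <- sc[[col]] * fx
  sc$mass <- sc$mass * fx^3
  for (col in c("ixx", "iyy", "izz")) sc[[col]] <- sc[[col]] * fx^5
  model$segments <- sc
  model$foot_cop <- model$foot_cop * f[["foot"]]
  for (a in names(model$mtus)) {
    via <- model$mtus[[a]]$path$via
    for (i in seq_len(nrow(via))) {
      fv <- f[[via$segment[i]]]
      via[i, c("x", "y", "z")] <- via[i, c("x", "y", "z")] * fv
    }
    model$mtus[[a]]$path$via <- via
  }
  L_new <- vapply(names(model$mtus),
                  function(a) mtu_length(model, qref, a), numeric(1))
  lambda <- L_new / L_old
  for (a in names(model$mtus)) {
    model$mtus[[a]]$params$l_opt <- model$mtus[[a]]$params$l_opt * lambda[[a]]
    model$mtus[[a]]$params$l_ts <- model$mtus[[a]]$params$l_ts * lambda[[a]]
  }
  if (!is.null(subject_mass)) {
    stopifnot(subject_mass > 0)
    model$segments$mass <- model$segments$mass *
      subject_mass / sum(model$segments$mass)
  }
  model
}

#' Fixed center of pressure in the foot frame
#'
#' The center of pressure of the ground reaction force is fixed for the whole
#' stance at the mid-point of the distal end of the metatarsals; an offset
#' along the foot's long (cranial-caudal) axis supports the sensitivity
#' analysis.
#'
#' @param model a `hindlimb_model`.
#' @param offset cranial(+)/caudal(-) shift along the foot axis, m.
#' @return length-3 point in the foot segment frame.
#' @export
fixed_cop <- function(model, offset = 0) {
  # The foot frame's -y axis points distally (cranially for a planted foot),
  # so a cranial offset moves the point further along -y.
  model$foot_cop + c(0, -offset, 0)
}
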