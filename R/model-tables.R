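#' Force-generating parameters of the hindlimb musculotendon units
#'
#' Published force-generating constants for the musculotendon units (MTUs) of
#' the mouse hindlimb model: maximum isometric force `f_max` (N), optimal
#' fiber length `l_opt` (m), tendon slack length `l_ts` (m) and pennation
#' angle at optimal fiber length `pennation0` (degrees). Each MTU belongs to
#' a functional group (hip rotators/adductors/flexors/extensors, knee
#' extensors/flexors, ankle dorsiflexors/plantarflexors/everters) which the
#' procedural path generator uses to fix the sign of its primary moment arm.
#'
#' `v_max` (maximal contractile velocity, optimal fiber lengths per second)
#' is a model input that the source table does not print; the configurable
#' default of 10 is attached here.
#'
#' @param v_max maximal contractile velocity in optimal fiber lengths per
#'   second attached to every MTU (default 10).
#' @return a data.frame with one row per MTU: `group`, `name`, `abbreviation`,
#'   `f_max`, `l_opt`, `l_ts`, `pennation0`, `v_max`.
#' @export
mtu_parameter_table <- function(v_max = 10) {
  stopifnot(v_max > 0)
  tab <- data.frame(
    group = rep(
      c("hip_rotator", "hip_adductor", "hip_flexor", "hip_extensor",
        "knee_extensor", "knee_flexor", "ankle_dorsiflexor",
        "ankle_plantarflexor", "ankle_everter"),
      times = c(4, 5, 4, 10, 4, 1, 3, 6, 5)
    ),
    name = c(
      "Obturator externus", "Obturator internus", "Gemellus",
      "Quadratus femoris",
      "Adductor magnus", "Adductor longus", "Adductor brevis",
      "Gracilis posterior", "Gracilis anterior",
      "Psoas major", "Psoas minor", "Iliacus", "Pectineus",
      "Gluteus maximus (dorsal)", "Gluteus maximus (middle)",
      "Gluteus maximus (ventral)", "Caudofemoralis", "Semimembranosus",
      "Semitendinosus", "Biceps femoris anterior",
      "Biceps femoris posterior (cranial)",
      "Biceps femoris posterior (middle)",
      "Biceps femoris posterior (caudal)",
      "Rectus femoris", "Vastus medialis", "Vastus lateralis",
      "Vastus intermedius",
      "Popliteus",
      "Tibialis anterior", "Extensor digitorum longus",
      "Extensor hallucis longus",
      "Medial gastrocnemius", "Lateral gastrocnemius", "Soleus",
      "Plantaris", "Flexor digitorum longus", "Tibialis posterior",
      "Peroneus longus", "Peroneus tertius", "Peroneus brevis",
      "Peroneus digiti quarti", "Peroneus digiti quinti"
    ),
    abbreviation = c(
      "OE", "OI", "GEM", "QF",
      "AM", "AL", "AB", "GP", "GA",
      "PMA", "PMI", "ILI", "PECT",
      "GM (d)", "GM (m)", "GM (v)", "CF", "SM", "ST", "BFA",
      "BFP (cr)", "BFP (m)", "BFP (ca)",
      "RF", "VM", "VL", "VI",
      "POP",
      "TA", "EDL", "EHL",
      "MG", "LG", "SOL", "PLANT", "FDL", "TP",
      "PL", "PT", "PB", "PDQA", "PDQI"
    ),
    f_max = c(
      0.086, 0.314, 0.179, 2.030,
      0.614, 0.402, 0.234, 0.345, 0.402,
      1.338, 1.088, 0.549, 0.363,
      0.936, 1.026, 1.049, 0.554, 1.916, 1.299, 0.876,
      0.725, 0.728, 0.611,
      4.162, 1.098, 2.828, 0.367,
      0.307,
      2.422, 0.368, 0.069,
      1.750, 3.784, 0.591, 0.880, 1.896, 0.549,
      0.647, 0.457, 0.396, 0.112, 0.102
    ),
    l_opt = c(
      0.00246, 0.00565, 0.00143, 0.00465,
      0.00760, 0.00745, 0.00642, 0.00912, 0.00882,
      0.00697, 0.00578, 0.00857, 0.00277,
      0.01305, 0.01271, 0.01242, 0.01137, 0.01165, 0.01111, 0.01145,
      0.01008, 0.01004, 0.01197,
      0.00534, 0.00653, 0.00681, 0.00606,
      0.00206,
      0.00490, 0.00635, 0.00593,
      0.00550, 0.00541, 0.00316, 0.00431, 0.00431, 0.00359,
      0.00378, 0.00339, 0.00229, 0.00393, 0.00362
    ),
    l_ts = c(
      0.00096, 0.00065, 0.00001, 0.00110,
      0.00302, 0.00255, 0.00176, 0.00435, 0.00607,
      0.00501, 0.00390, 0.00275, 0.00181,
      0.00501, 0.00489, 0.00478, 0.00307, 0.00409, 0.00480, 0.00383,
      0.00491, 0.00478, 0.00406,
      0.00853, 0.00768, 0.00735, 0.00702,
      0.00203,
      0.01180, 0.02378, 0.01793,
      0.01395, 0.01389, 0.00740, 0.01517, 0.02761, 0.01500,
      0.01408, 0.01122, 0.01005, 0.02357, 0.01959
    ),
    pennation0 = c(
      0.00, 0.00, 0.00, 0.00,
      0.00, 0.00, 0.00, 0.00, 0.00,
      15.54, 12.57, 0.00, 15.18,
      20.42, 20.42, 20.42, 0.00, 0.00, 0.00, 0.00,
      0.00, 0.00, 0.00,
      15.89, 16.15, 15.53, 10.92,
      0.00,
      16.58, 12.39, 9.56,
      14.24, 17.28, 11.43, 17.10, 15.20, 15.44,
      14.90, 12.46, 11.46, 12.42, 9.44
    ),
    stringsAsFactors = FALSE
  )
  tab$v_max <- v_max
  tab
}

#' Masses and inertial properties of the torso and hindlimb segments
#'
#' Published segment inertial properties used to simulate trotting: mass (kg),
#' center-of-mass offset in the segment frame (m) and principal moments of
#' inertia about the center of mass (kg m^2). Center-of-mass offsets are kept
#' exactly as printed (the source lists them in mm as x, y, z triplets);
#' `com_chain` maps each into the planar-chain segment frame used by this
#' package (origin at the proximal joint, -y toward the distal joint,
#' z medio-lateral) -- for the foot the printed long axis is x and is rotated
#' onto the chain's -y axis.
#'
#' Segment `length` (proximal-to-distal joint distance) is not printed; the
#' defaults here are model choices consistent with the printed center-of-mass
#' offsets (mid-segment CoM for thigh and lower leg) and are the lengths used
#' by the procedural muscle-path geometry.
#'
#' @return a data.frame with one row per segment: `name`, `mass` (kg),
#'   `com_x/y/z` (m, as printed), `ixx/iyy/izz` (kg m^2), `length` (m),
#'   `chain_x/chain_y` (m, CoM in the planar chain frame).
#' @export
segment_inertia_table <- function() {
  tab <- data.frame(
    name = c("torso", "pelvis", "thigh", "lower_leg", "foot"),
    mass = c(19.5, 0.38, 0.44, 0.21, 0.063) * 1e-3,
    com_x = c(29.4, 2.9, -2.8, -0.8, 4.5) * 1e-3,
    com_y = c(-4.1, -1.2, -7.2, -7.2, -0.20) * 1e-3,
    com_z = c(-1.5, 2.4, 0.20, 0.0, 0.10) * 1e-3,
    ixx = c(1.07e-6, 2.35e-9, 6.83e-9, 3.73e-9, 6.10e-11),
    iyy = c(9.43e-6, 6.43e-9, 4.23e-9, 6.80e-10, 1.26e-9),
    izz = c(9.12e-6, 6.70e-9, 9.10e-9, 4.10e-9, 1.26e-9),
    length = c(0.0588, 0.0100, 0.0144, 0.0144, 0.0090),
    stringsAsFactors = FALSE
  )
  # CoM in the planar chain frame: torso/pelvis frames are axis-aligned with
  # the chain frame; thigh and lower leg already use y along the segment; the
  # foot's printed frame has x distal, rotated here onto -y.
  tab$chain_x <- tab$com_x
  tab$chain_y <- tab$com_y
  foot <- tab$name == "foot"
  tab$chain_x[foot] <- tab$com_y[foot]
  tab$chain_y[foot] <- -tab$com_x[foot]
  tab
}
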