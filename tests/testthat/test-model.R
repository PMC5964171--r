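# Musculoskeletal model: published tables, procedural geometry contracts,
# moment arms, scaling.

test_that("default model carries the published MTU and segment tables", {
  m <- test_model()
  expect_equal(m$mtus$RF$params$f_max, 4.162)
  expect_equal(m$mtus$RF$params$l_opt, 0.00534)
  expect_equal(m$mtus$RF$params$l_ts, 0.00853)
  expect_equal(m$mtus$RF$params$pennation0, 15.89)
  expect_equal(m$segments$mass[m$segments$name == "foot"], 6.3e-5)
  # the printed table has 42 rows (the source text also cites a 44-MTU
  # model; two rows are absent from the printed table -- see vignette)
  expect_length(m$mtus, 42)
  expect_equal(nrow(mtu_parameter_table()), 42)
  # total limb mass = pelvis + thigh + lower leg + foot as printed (grams)
  limb <- m$segments$mass[m$segments$name != "torso"]
  expect_equal(sum(limb) * 1e3, 0.38 + 0.44 + 0.21 + 0.063)
})

test_that("segment inertias are physically realizable", {
  sg <- segment_inertia_table()
  expect_true(all(sg$mass > 0))
  expect_true(all(sg$ixx + sg$iyy >= sg$izz))
  expect_true(all(sg$iyy + sg$izz >= sg$ixx))
  expect_true(all(sg$izz + sg$ixx >= sg$iyy))
  expect_true(all(sg$length > 0))
})

test_that("reference-pose MTU length equals l_ts + l_opt cos(pennation)", {
  m <- test_model()
  q0 <- reference_pose(m)
  for (a in names(m$mtus)) {
    p <- m$mtus[[a]]$params
    expect_equal(mtu_length(m, q0, a),
                 p$l_ts + p$l_opt * cos(p$pennation0 * pi / 180),
                 tolerance = 1e-12)
  }
  # the RF value in closed form (= 0.0136660 m)
  expect_equal(mtu_length(m, q0, "RF"),
               0.00853 + 0.00534 * cos(15.89 * pi / 180), tolerance = 1e-12)
})

test_that("moment-arm signs match the functional groups", {
  m <- test_model()
  qc <- mousegait:::calibration_pose(m)
  for (a in names(m$mtus)) {
    path <- m$mtus[[a]]$path
    r <- moment_arm(m, qc, a, path$primary)
    expect_equal(sign(r), path$primary_sign,
                 label = sprintf("%s about %s", a, path$primary))
  }
})

test_that("mtu_length handles custom paths and errors", {
  m <- test_model()
  # two via points on the same segment, 5 mm apart: rigid distance at any q
  via <- data.frame(segment = c("thigh", "thigh"), x = c(0, 0),
                    y = c(-0.001, -0.006), z = c(0, 0))
  m2 <- add_custom_mtu(m, "RIGID", via, spanned = character(0))
  for (q in list(reference_pose(m), test_pose()))
    expect_equal(mtu_length(m2, q, "RIGID"), 0.005)
  expect_mousegait_error(mtu_length(m, reference_pose(m), "NOPE"),
                         "mousegait_input_error")
  qbad <- reference_pose(m); qbad["hip_flexion"] <- 3
  expect_mousegait_error(mtu_length(m, qbad, "RF"),
                         "mousegait_range_violation")
})

test_that("length is invariant to coordinates the MTU does not span", {
  m <- test_model()
  q <- test_pose()
  L0 <- mtu_length(m, q, "LG")       # ankle muscle
  q2 <- q; q2["hip_flexion"] <- 0.2; q2["pelvic_tilt"] <- 0.0
  expect_equal(mtu_length(m, q2, "LG"), L0, tolerance = 1e-14)
  expect_equal(moment_arm(m, q, "LG", "hip_flexion"), 0, tolerance = 1e-10)
  expect_equal(moment_arm(m, q, "RF", "ankle_flexion"), 0, tolerance = 1e-10)
  # pelvic tilt rotates the whole limb: no MTU spans it
  for (a in c("RF", "SM", "LG"))
    expect_equal(moment_arm(m, q, a, "pelvic_tilt"), 0, tolerance = 1e-10)
})

test_that("straight path across a hinge has pulley moment arm |r| = d", {
  m <- test_model()
  d <- 0.002
  # both endpoints at perpendicular (dorsal) distance d from the knee axis,
  # path parallel to the reference limb axis
  Tref <- segment_transforms(m, reference_pose(m))
  lth <- m$segments$length[m$segments$name == "thigh"]
  A_w <- c(-lth + 0.004, d, 0)
  B_w <- c(-lth - 0.004, d, 0)
  A_l <- solve(Tref$thigh) %*% c(A_w, 1)
  B_l <- solve(Tref$lower_leg) %*% c(B_w, 1)
  via <- data.frame(segment = c("thigh", "lower_leg"),
                    x = c(A_l[1], B_l[1]), y = c(A_l[2], B_l[2]),
                    z = c(A_l[3], B_l[3]))
  m2 <- add_custom_mtu(m, "PULLEY", via, spanned = "knee_extension")
  r <- moment_arm(m2, reference_pose(m), "PULLEY", "knee_extension")
  expect_equal(abs(r), d, tolerance = 1e-6)
})

test_that("virtual-work moment arms match a Richardson-extrapolated oracle", {
  m <- test_model()
  set.seed(11)
  co <- m$coordinates
  for (rep in 1:6) {
    q <- stats::setNames(
      stats::runif(nrow(co), co$lower * 0.5, co$upper * 0.5), co$name)
    mtu <- sample(names(m$mtus), 1)
    coord <- sample(m$mtus[[mtu]]$path$spanned, 1)
    r <- moment_arm(m, q, mtu, coord)
    # independent oracle: Richardson extrapolation at two smaller steps
    f <- function(h) {
      qp <- q; qm <- q
      qp[coord] <- qp[coord] + h; qm[coord] <- qm[coord] - h
      -(mtu_length(m, qp, mtu, check_range = FALSE) -
          mtu_length(m, qm, mtu, check_range = FALSE)) / (2 * h)
    }
    r_rich <- (4 * f(5e-7) - f(1e-6)) / 3
    expect_lt(abs(r - r_rich), 1e-7)
  }
})

test_that("scaling follows geometric similarity and round-trips", {
  m <- test_model()
  # identity
  m1 <- scale_model(m, c(thigh = 1))
  expect_equal(m1$segments, m$segments)
  expect_equal(m1$mtus$RF$params$l_opt, m$mtus$RF$params$l_opt)
  # published factors: thigh length x1.065
  f <- paper_scale_factors()
  ms <- scale_model(m, f)
  expect_equal(ms$segments$length[ms$segments$name == "thigh"],
               1.065 * m$segments$length[m$segments$name == "thigh"])
  # factor 2 on one segment: mass x8, Izz x32
  m2 <- scale_model(m, c(thigh = 2))
  i <- m$segments$name == "thigh"
  expect_equal(m2$segments$mass[i], 8 * m$segments$mass[i])
  expect_equal(m2$segments$izz[i], 32 * m$segments$izz[i])
  # normalized fiber length preserved at the reference pose
  q0 <- reference_pose(m)
  for (a in c("RF", "SM", "LG")) {
    st <- rigid_tendon_fiber_state(ms$mtus[[a]]$params, mtu_length(ms, q0, a))
    expect_equal(st$norm_fiber_length, 1, tolerance = 1e-9)
  }
  # f then 1/f recovers the original within 1e-12 relative
  mr <- scale_model(scale_model(m, f), 1 / f)
  for (a in names(m$mtus)) {
    expect_equal(mr$mtus[[a]]$params$l_opt, m$mtus[[a]]$params$l_opt,
                 tolerance = 1e-12)
    expect_equal(mr$mtus[[a]]$params$l_ts, m$mtus[[a]]$params$l_ts,
                 tolerance = 1e-12)
  }
  expect_equal(mr$segments$mass, m$segments$mass, tolerance = 1e-12)
  expect_mousegait_error(scale_model(m, c(thigh = -1)),
                         "mousegait_input_error")
  # subject-mass renormalization
  mm <- scale_model(m, f, subject_mass = 0.0187)
  expect_equal(sum(mm$segments$mass), 0.0187)
})

test_that("fixed CoP offsets are linear along the foot axis", {
  m <- test_model()
  expect_equal(fixed_cop(m, 0), m$foot_cop)
  up <- fixed_cop(m, 0.002)
  dn <- fixed_cop(m, -0.002)
  expect_equal((up + dn) / 2, m$foot_cop)
  expect_equal(up[2] - m$foot_cop[2], -0.002)  # cranial = distal = -y
})
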