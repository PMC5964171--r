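# Shared fixtures. The default model is deterministic and moderately
# expensive to build (sign calibration), so it is constructed once per
# test run; tests that mutate it must copy first (plain list semantics
# make that automatic on assignment).

.fixtures <- new.env(parent = emptyenv())

test_model <- function() {
  if (is.null(.fixtures$model)) .fixtures$model <- build_default_model()
  .fixtures$model
}

test_curves <- function() {
  if (is.null(.fixtures$curves)) .fixtures$curves <- default_muscle_curves()
  .fixtures$curves
}

# A mid-gait pose with every coordinate engaged.
test_pose <- function() {
  c(pelvic_tilt = 0.15, hip_flexion = 0.7, hip_adduction = 0.1,
    knee_extension = -0.8, ankle_flexion = 0.2)
}

# Model stripped to a single massive segment (uniform-rod style thigh
# pendulum about the hip): everything else massless and inertia-free.
pendulum_model <- function() {
  m <- test_model()
  keep <- m$segments$name == "thigh"
  m$segments$mass[!keep] <- 0
  m$segments$izz[!keep] <- 0
  m$segments$ixx[] <- 0
  m$segments$iyy[] <- 0
  m
}

massless_model <- function() {
  m <- test_model()
  m$segments$mass[] <- 0
  m$segments$izz[] <- 0
  m$segments$ixx[] <- 0
  m$segments$iyy[] <- 0
  m
}

# Reduced actuation: one independent muscle per actuated limb coordinate
# (unique static-optimization solution for recovery oracles).
reduced_model <- function() {
  m <- test_model()
  m$mtus <- m$mtus[c("SM", "RF", "LG")]
  m
}

# Custom two-point MTU on one segment / across one hinge for geometric
# oracle tests.
add_custom_mtu <- function(model, label, via, spanned,
                           params = list(name = label, abbreviation = label,
                                         f_max = 1, l_opt = 0.005,
                                         l_ts = 0.001, pennation0 = 0,
                                         v_max = 10)) {
  model$mtus[[label]] <- list(params = params,
                              path = list(via = via, spanned = spanned,
                                          primary = spanned[1],
                                          primary_sign = 1))
  model
}

expect_mousegait_error <- function(expr, class) {
  expect_error(expr, class = class)
}
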