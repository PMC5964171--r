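#' @keywords internal
"_PACKAGE"

# Degrees <-> radians. Angles are radians internally; degrees at interfaces
# (the published muscle table prints pennation in degrees).
deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Wrap an angle difference into (-pi, pi].
wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y <= -pi] <- y[y <= -pi] + 2 * pi
  y
}

# 3x3 rotation matrices about the frame axes (z = medio-lateral, out of the
# sagittal plane; x = cranial; y = dorsal).
rot_z <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3)
}
rot_x <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(1, 0, 0, 0, ca, sa, 0, -sa, ca), 3, 3)
}

# Homogeneous 4x4 transform from rotation R and translation t.
htransform <- function(R = diag(3), t = c(0, 0, 0)) {
  T <- diag(4)
  T[1:3, 1:3] <- R
  T[1:3, 4] <- t
  T
}

# Apply homogeneous transform to a 3-vector (or 3 x n matrix of columns).
happly <- function(T, p) {
  p <- as.matrix(p)
  if (nrow(p) != 3) p <- t(p)
  sweep(T[1:3, 1:3] %*% p, 1, -T[1:3, 4], "-")
}

# Run an expression with a fixed RNG seed, restoring the caller's RNG state.
# All stochastic generators in the package route randomness through this so
# identical (params, seed) give byte-identical output.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Classed error signals so callers can distinguish contract violations.
stop_mousegait <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "mousegait_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

# Central-difference derivative of f at x (scalar step per component).
central_diff <- function(f, x, h = 1e-5) {
  (f(x + h) - f(x - h)) / (2 * h)
}

# Central differences of a sampled series y(t) on a uniform grid; endpoints
# use one-sided second-order stencils so output length equals input length.
series_deriv <- function(y, dt) {
  n <- length(y)
  if (n < 3) stop_mousegait("mousegait_input_error", "series too short to differentiate")
  d <- numeric(n)
  d[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (2 * dt)
  d[1] <- (-3 * y[1] + 4 * y[2] - y[3]) / (2 * dt)
  d[n] <- (3 * y[n] - 4 * y[n - 1] + y[n - 2]) / (2 * dt)
  d
}

# Trapezoidal integral of y over t.
trapz <- function(t, y) {
  n <- length(t)
  if (n < 2) return(0)
  sum((y[-1] + y[-n]) * diff(t)) / 2
}

`%||%` <- function(a, b) if (is.null(a)) b else a
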