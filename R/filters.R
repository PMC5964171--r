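# Zero-phase Butterworth low-pass filtering.
#
# No digital-filter package ships with the supported environment, so the
# classic design is implemented here: analog Butterworth prototype poles,
# frequency pre-warp, bilinear transform, and forward-backward application
# with steady-state initial conditions (so constants pass through exactly)
# and odd-reflection edge padding.

# Polynomial coefficients (descending powers) from roots, real part.
poly_from_roots <- function(r) {
  p <- 1
  for (ri in r) p <- c(p, 0) - c(0, p) * ri
  Re(p)
}

#' Digital Butterworth low-pass coefficients
#'
#' @param order filter order per pass.
#' @param cutoff cutoff frequency, Hz.
#' @param fs sampling rate, Hz.
#' @return list with numerator `b` and denominator `a` (a\[1\] = 1).
#' @export
butter_lowpass <- function(order, cutoff, fs) {
  if (cutoff <= 0 || cutoff >= fs / 2)
    stop_mousegait("mousegait_input_error",
                   "cutoff must lie in (0, Nyquist)")
  k <- seq_len(order)
  # analog prototype poles on the unit left half circle
  theta <- pi * (2 * k + order - 1) / (2 * order)
  p_analog <- complex(modulus = 1, argument = theta)
  warped <- 2 * fs * tan(pi * cutoff / fs)
  p_analog <- p_analog * warped
  # bilinear transform
  p_digital <- (2 * fs + p_analog) / (2 * fs - p_analog)
  a <- poly_from_roots(p_digital)
  b <- poly_from_roots(rep(-1 + 0i, order))
  b <- b * sum(a) / sum(b)  # unit DC gain
  list(b = b, a = a)
}

# Direct-form II transposed filtering with initial state zi (per unit input).
lfilter <- function(b, a, x, zi = NULL) {
  n <- length(a) - 1
  z <- if (is.null(zi)) numeric(n) else zi
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    yi <- b[1] * x[i] + z[1]
    if (n > 1) {
      for (j in seq_len(n - 1))
        z[j] <- b[j + 1] * x[i] + z[j + 1] - a[j + 1] * yi
    }
    z[n] <- b[n + 1] * x[i] - a[n + 1] * yi
    y[i] <- yi
  }
  y
}

# Steady-state filter state for a unit-step input (scipy lfilter_zi).
lfilter_zi <- function(b, a) {
  n <- length(a) - 1
  A <- matrix(0, n, n)
  A[, 1] <- -a[-1]
  if (n > 1) A[cbind(1:(n - 1), 2:n)] <- 1
  B <- b[-1] - b[1] * a[-1]
  solve(diag(n) - A, B)
}

#' Zero-phase Butterworth low-pass filter
#'
#' Forward-backward (zero-phase) Butterworth filtering, order 4 per pass by
#' default, with odd-reflection padding and steady-state initial conditions.
#' The effective magnitude response is the squared single-pass response.
#'
#' @param x numeric vector, or matrix/data.frame filtered column-wise.
#' @param fs sampling rate, Hz.
#' @param cutoff cutoff frequency, Hz (default 20, the gait-standard value).
#' @param order Butterworth order per pass (default 4).
#' @return filtered series, same shape as `x`.
#' @export
lowpass_filter <- function(x, fs, cutoff = 20, order = 4) {
  if (is.data.frame(x)) {
    x[] <- lapply(x, lowpass_filter, fs = fs, cutoff = cutoff, order = order)
    return(x)
  }
  if (is.matrix(x))
    return(apply(x, 2, lowpass_filter, fs = fs, cutoff = cutoff,
                 order = order))
  coefs <- butter_lowpass(order, cutoff, fs)
  b <- coefs$b; a <- coefs$a
  npad <- min(length(x) - 1, max(3 * (length(a) - 1), 12))
  if (npad < 1)
    stop_mousegait("mousegait_input_error", "series too short to filter")
  # odd reflection about the end points
  pre <- 2 * x[1] - x[seq(npad + 1, 2)]
  post <- 2 * x[length(x)] - x[seq(length(x) - 1, length(x) - npad)]
  ext <- c(pre, x, post)
  zi <- lfilter_zi(b, a)
  y <- lfilter(b, a, ext, zi * ext[1])
  y <- rev(lfilter(b, a, rev(y), zi * y[length(y)]))
  y[(npad + 1):(npad + length(x))]
}
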