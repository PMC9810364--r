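# Minimal IIR design + zero-phase filtering + analytic signal.
#
# No DSP dependency is available in the target environment, so the three
# primitives the pipeline needs are implemented here: a Butterworth
# band-pass designed by the classical analog-prototype -> lp2bp ->
# bilinear route (identical to the scipy/Matlab `butter` path), a
# forward-backward `filtfilt` with odd-reflection padding and
# steady-state initial conditions, and an FFT Hilbert transform.

# polynomial coefficients (descending powers) from roots, complex-safe
poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (rt in r) p <- c(p, 0) - c(0, p * rt)
  p
}

#' Design an order-n digital Butterworth band-pass filter
#'
#' Analog Butterworth prototype transformed to a band-pass (which doubles
#' the pole count: order 3 gives a 6-pole digital filter) and discretized
#' by the bilinear transform with frequency pre-warping.
#'
#' @param low,high Band edges in Hz.
#' @param rate Sampling rate in Hz.
#' @param order Prototype order (default 3).
#' @return List with numerator `b` and denominator `a` coefficients.
#' @export
butter_bandpass <- function(low, high, rate, order = 3) {
  if (!(low > 0 && high > low && high < rate / 2))
    param_error("band (%g, %g) Hz must lie inside (0, rate/2 = %g)",
                low, high, rate / 2)
  n <- as.integer(order)
  k <- seq_len(n)
  p <- exp(1i * pi * (2 * k + n - 1) / (2 * n))  # unit-cutoff poles
  g <- 1
  # pre-warp normalized edges (fs = 2 convention)
  fs <- 2
  w1 <- 2 * low / rate
  w2 <- 2 * high / rate
  warped1 <- 2 * fs * tan(pi * w1 / fs)
  warped2 <- 2 * fs * tan(pi * w2 / fs)
  bw <- warped2 - warped1
  wo <- sqrt(warped1 * warped2)
  # low-pass -> band-pass (zeros at origin appear, poles double)
  p_lp <- p * bw / 2
  p_bp <- c(p_lp + sqrt(p_lp^2 - wo^2), p_lp - sqrt(p_lp^2 - wo^2))
  z_bp <- rep(0 + 0i, n)
  k_bp <- g * bw^n
  # bilinear transform
  fs2 <- 2 * fs
  p_d <- (fs2 + p_bp) / (fs2 - p_bp)
  z_d <- (fs2 + z_bp) / (fs2 - z_bp)
  z_d <- c(z_d, rep(-1 + 0i, length(p_bp) - length(z_bp)))
  k_d <- k_bp * Re(prod(fs2 - z_bp) / prod(fs2 - p_bp))
  b <- Re(poly_from_roots(z_d)) * k_d
  a <- Re(poly_from_roots(p_d))
  list(b = b, a = a)
}

# steady-state initial conditions for cpp_lfilter (step-response match)
lfilter_zi <- function(b, a) {
  nf <- max(length(a), length(b))
  a <- c(a, rep(0, nf - length(a)))
  b <- c(b, rep(0, nf - length(b)))
  b <- b / a[1]
  a <- a / a[1]
  ns <- nf - 1
  # companion matrix of a
  comp <- matrix(0, ns, ns)
  comp[1, ] <- -a[-1]
  if (ns > 1) comp[cbind(2:ns, 1:(ns - 1))] <- 1
  rhs <- b[-1] - a[-1] * b[1]
  solve(diag(ns) - t(comp), rhs)
}

#' Zero-phase forward-backward IIR filtering
#'
#' Applies the filter forward and reversed, cancelling phase distortion.
#' The signal is extended at both ends by odd reflection over
#' `3 * (nfilt - 1)` samples and the filter is started from scaled
#' steady-state conditions, suppressing edge transients.
#'
#' @param b,a Filter coefficients.
#' @param x Numeric signal.
#' @return Filtered signal, same length as `x`.
#' @export
filtfilt_iir <- function(b, a, x) {
  nf <- max(length(a), length(b))
  padlen <- 3 * (nf - 1)
  if (length(x) <= padlen)
    param_error("signal length %d too short for filter warm-up (%d samples)",
                length(x), padlen)
  zi <- lfilter_zi(b, a)
  ext <- c(2 * x[1] - x[(padlen + 1):2],
           x,
           2 * x[length(x)] - x[(length(x) - 1):(length(x) - padlen)])
  y <- cpp_lfilter(b, a, ext, zi * ext[1])
  y <- rev(y)
  y <- cpp_lfilter(b, a, y, zi * y[1])
  y <- rev(y)
  y[(padlen + 1):(padlen + length(x))]
}

#' Analytic signal via the FFT Hilbert transform
#'
#' @param x Real signal.
#' @return Complex vector `x + i * H(x)`.
#' @export
hilbert_analytic <- function(x) {
  n <- length(x)
  if (n < 2) param_error("signal too short for analytic signal")
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}
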