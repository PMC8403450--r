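# Digital Butterworth low-pass filtering.
#
# Coefficients come from the bilinear transform of the analog Butterworth
# prototype (poles on the left unit semicircle), so the single-pass response
# is the textbook |H(f)|^2 = 1 / (1 + (f_w/f_cw)^(2n)) in prewarped
# frequency. Event detection must not be lag-shifted, so the user-facing
# filter runs forward-backward (zero phase) with odd-reflection padding and
# steady-state initial conditions; the effective magnitude response is the
# square of the single-pass one (steeper than the nominal order).

#' Butterworth low-pass coefficients
#'
#' @param order filter order (analog prototype order; single pass).
#' @param cutoff -3 dB cutoff frequency, Hz.
#' @param fs sampling frequency, Hz; `cutoff` must be below `fs/2`.
#' @return list with numerator `b` and denominator `a` (monic) of the
#'   discrete transfer function in z^-1.
#' @export
butter_lowpass <- function(order, cutoff, fs) {
  if (order < 1L) stop("parameter error: order must be >= 1")
  if (cutoff <= 0 || cutoff >= fs / 2)
    stop("parameter error: cutoff must satisfy 0 < cutoff < fs/2")
  warp <- tan(pi * cutoff / fs)
  k <- seq_len(order)
  # analog prototype poles scaled to the prewarped cutoff
  p <- warp * exp(1i * pi * (2 * k + order - 1) / (2 * order))
  # bilinear transform: zeros at z = -1, poles (1+p)/(1-p)
  zp <- (1 + p) / (1 - p)
  a <- 1
  for (r in zp) a <- c(a, 0) - c(0, a * r)
  b <- 1
  for (i in k) b <- c(b, 0) + c(0, b)    # (1 + z^-1)^order
  gain <- prod(-p) / prod(1 - p)
  list(b = Re(gain) * b, a = Re(a))
}

#' Single-pass IIR filtering (direct form II transposed)
#'
#' @param b,a transfer-function coefficients, `a[1]` normalised to 1.
#' @param x numeric signal.
#' @param zi optional initial filter state (length `max(length(a),
#'   length(b)) - 1`).
#' @return filtered signal, same length as `x`.
#' @export
iir_filter <- function(b, a, x, zi = NULL) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b))) / a[1]
  a <- c(a, rep(0, n - length(a))) / a[1]
  z <- if (is.null(zi)) rep(0, n - 1L) else zi
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    xi <- x[i]
    yi <- b[1] * xi + z[1]
    if (n > 2L)
      for (j in seq_len(n - 2L))
        z[j] <- b[j + 1L] * xi + z[j + 1L] - a[j + 1L] * yi
    z[n - 1L] <- b[n] * xi - a[n] * yi
    y[i] <- yi
  }
  y
}

# Steady-state filter state for a unit-step input (removes start-up
# transients when scaled by the first signal value).
iir_filter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b))) / a[1]
  a <- c(a, rep(0, n - length(a))) / a[1]
  if (n == 1L) return(numeric(0))
  comp <- matrix(0, n - 1L, n - 1L)          # companion matrix of a
  comp[1, ] <- -a[-1]
  if (n > 2L) comp[cbind(2:(n - 1L), 1:(n - 2L))] <- 1
  B <- b[-1] - a[-1] * b[1]
  solve(diag(n - 1L) - t(comp), B)
}

#' Zero-phase filtering (forward-backward)
#'
#' Applies the filter forward then backward so events keep their timing.
#' Edges are handled by odd reflection of three filter lengths at each end
#' plus steady-state initial conditions.
#'
#' @param b,a filter coefficients.
#' @param x numeric signal; must be longer than three filter lengths.
#' @return zero-phase filtered signal.
#' @export
filtfilt_zero_phase <- function(b, a, x) {
  n <- max(length(a), length(b))
  pad <- 3L * (n - 1L)
  if (length(x) <= pad)
    stop("signal too short for zero-phase filtering (need > 3 x order)")
  ext <- c(2 * x[1] - x[(pad + 1L):2L], x,
           2 * x[length(x)] - x[(length(x) - 1L):(length(x) - pad)])
  zi <- iir_filter_zi(b, a)
  y <- iir_filter(b, a, ext, zi * ext[1])
  y <- rev(iir_filter(b, a, rev(y), zi * y[length(y)]))
  y[(pad + 1L):(pad + length(x))]
}

#' Low-pass filter a uniform series (zero phase)
#'
#' @param x a [uniform_series()].
#' @param order Butterworth order of each pass (default 4).
#' @param cutoff cutoff frequency, Hz.
#' @return filtered series with unchanged grid; DC content is preserved.
#' @export
butterworth_lowpass <- function(x, order = 4L, cutoff) {
  stopifnot(inherits(x, "uniform_series"))
  coef <- butter_lowpass(order, cutoff, x$fs)
  if (nrow(x$values) <= 3L * order)
    stop("series length must exceed 3 x filter order")
  out <- apply(x$values, 2L, function(col)
    filtfilt_zero_phase(coef$b, coef$a, col))
  uniform_series(out, fs = x$fs, t0 = x$t0, label = x$label)
}
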