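# Butterworth low-pass design and zero-phase filtering.
#
# The analysis chain needs a conventional posturography filter (zero-phase
# low-pass before differentiation) and the simulator needs a causal low-pass
# to shape exploratory noise. Neither is available in the package's
# dependency set, so both are implemented here from the standard digital
# Butterworth design (analog prototype poles, bilinear transform with
# frequency prewarping) and are oracle-tested against analytic magnitude
# responses.

#' Digital Butterworth low-pass coefficients
#'
#' Designs an order-`order` digital Butterworth low-pass filter by bilinear
#' transform of the analog prototype, with the cutoff prewarped so the -3 dB
#' point lands exactly at `cutoff`.
#'
#' @param order Filter order (positive integer).
#' @param cutoff -3 dB cutoff frequency in Hz.
#' @param fs Sampling rate in Hz; `cutoff` must be below `fs / 2`.
#' @return List with numerator `b` and denominator `a` coefficient vectors
#'   (`a[1] == 1`), usable with [filter_ba()] and [filtfilt()].
#' @export
butter_lowpass <- function(order, cutoff, fs) {
  check_number(order, "order", lower = 1, upper = 12)
  check_number(cutoff, "cutoff", lower = 0, strict_lower = TRUE)
  check_number(fs, "fs", lower = 0, strict_lower = TRUE)
  if (cutoff >= fs / 2) stop_user("cutoff must be below the Nyquist frequency fs/2")
  order <- as.integer(order)
  # analog prototype poles on the unit circle, left half-plane
  k <- seq_len(order)
  theta <- pi * (2 * k - 1) / (2 * order) + pi / 2
  p_analog <- complex(modulus = 1, argument = theta)
  # prewarp and scale
  warped <- 2 * fs * tan(pi * cutoff / fs)
  p_analog <- p_analog * warped
  # bilinear transform z = (2 fs + s) / (2 fs - s)
  p_z <- (2 * fs + p_analog) / (2 * fs - p_analog)
  # 'order' zeros at z = -1
  b <- Re(poly_from_roots(rep(-1 + 0i, order)))
  a <- Re(poly_from_roots(p_z))
  # unit DC gain
  gain <- sum(a) / sum(b)
  list(b = b * gain, a = a)
}

# polynomial coefficients (descending powers) from roots
poly_from_roots <- function(r) {
  coef <- 1 + 0i
  for (ri in r) coef <- c(coef, 0i) - c(0i, coef * ri)
  coef
}

#' Apply an IIR filter (causal, zero initial state)
#'
#' Direct-form difference equation
#' `y[n] = sum(b * x[n:(n-nb)]) - sum(a[-1] * y[(n-1):(n-na)])`,
#' evaluated with zero initial conditions.
#'
#' @param b,a Coefficient vectors as returned by [butter_lowpass()].
#' @param x Numeric input series.
#' @return Filtered series, same length as `x`.
#' @export
filter_ba <- function(b, a, x) {
  if (abs(a[1] - 1) > 1e-12) {
    b <- b / a[1]
    a <- a / a[1]
  }
  nb <- length(b)
  # moving-average part with left zero padding
  xp <- c(rep(0, nb - 1L), x)
  u <- stats::filter(xp, b, method = "convolution", sides = 1)
  u <- as.numeric(u)[nb - 1L + seq_along(x)]
  if (length(a) > 1L) {
    y <- stats::filter(u, -a[-1], method = "recursive",
                       init = rep(0, length(a) - 1L))
    as.numeric(y)
  } else {
    u
  }
}

#' Zero-phase (forward-backward) filtering
#'
#' Applies the filter forwards then backwards, with odd-reflection end
#' padding so start-up transients decay inside the padding rather than in
#' the data. DC gain is exactly preserved; phase response is zero.
#'
#' @inheritParams filter_ba
#' @param padlen Number of reflected samples prepended/appended at each end;
#'   default scales with the filter order and is capped at `length(x) - 1`.
#' @return Filtered series, same length as `x`.
#' @export
filtfilt <- function(b, a, x, padlen = NULL) {
  n <- length(x)
  if (n < 4L) stop_user("series too short to filter (need >= 4 samples)")
  p <- padlen %||% max(3L * (max(length(a), length(b)) - 1L), 100L)
  p <- min(p, n - 1L)
  # odd reflection about the end values
  head_ext <- 2 * x[1] - x[(p + 1L):2L]
  tail_ext <- 2 * x[n] - x[(n - 1L):(n - p)]
  xe <- c(head_ext, x, tail_ext)
  y <- filter_ba(b, a, xe)
  y <- rev(filter_ba(b, a, rev(y)))
  y[(p + 1L):(p + n)]
}

#' Zero-phase Butterworth low-pass
#'
#' Convenience wrapper combining [butter_lowpass()] and [filtfilt()]. This
#' is the shared filtering operation used throughout the analysis chain
#' (markers and forces at 10 Hz, positions at 5 Hz before double
#' differentiation, by default).
#'
#' @param x Numeric series to filter.
#' @param cutoff -3 dB cutoff in Hz (must be below `fs / 2`).
#' @param fs Sampling rate in Hz.
#' @param order Butterworth order of each pass (default 4); the effective
#'   attenuation is doubled by the two passes.
#' @return Filtered series, same length as `x`.
#' @export
lowpass <- function(x, cutoff, fs, order = 4) {
  ba <- butter_lowpass(order, cutoff, fs)
  filtfilt(ba$b, ba$a, x)
}

# causal low-pass used by the simulator's noise shaping
causal_lowpass <- function(x, cutoff, fs, order = 2) {
  ba <- butter_lowpass(order, cutoff, fs)
  filter_ba(ba$b, ba$a, x)
}
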