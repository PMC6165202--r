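# Low-level signal primitives shared across modules. The inner IIR loop is
# compiled (src/iir.cpp); filter design stays in signal::butter.

#' Design a Butterworth filter
#'
#' Thin wrapper around [signal::butter()] returning transfer-function
#' coefficients for a lowpass, highpass or bandpass design.
#'
#' @param lo,hi Band edges in Hz. Supply both for a bandpass, only `hi` for a
#'   lowpass, only `lo` for a highpass.
#' @param fs Sampling rate in Hz.
#' @param order Design order of the filter.
#' @return A list with elements `b` and `a` (numerator / denominator
#'   coefficients).
#' @keywords internal
butter_design <- function(lo = NULL, hi = NULL, fs, order = 4) {
  nyq <- fs / 2
  if (!is.null(lo) && !is.null(hi)) {
    if (!(lo > 0 && lo < hi && hi < nyq)) {
      abort(sprintf("invalid band edges [%g, %g] Hz at fs = %g Hz", lo, hi, fs))
    }
    flt <- signal::butter(order, c(lo, hi) / nyq, type = "pass")
  } else if (!is.null(hi)) {
    if (!(hi > 0 && hi < nyq)) abort("invalid lowpass edge")
    flt <- signal::butter(order, hi / nyq, type = "low")
  } else if (!is.null(lo)) {
    if (!(lo > 0 && lo < nyq)) abort("invalid highpass edge")
    flt <- signal::butter(order, lo / nyq, type = "high")
  } else {
    abort("supply at least one band edge")
  }
  list(b = as.numeric(flt$b), a = as.numeric(flt$a))
}

# One causal IIR pass (compiled kernel).
iir_pass <- function(b, a, x) iir_filter_cpp(b, a, x)

#' Zero-phase (forward-backward) IIR filtering
#'
#' Applies the filter forwards and backwards so the net phase response is
#' zero and the magnitude response is squared. Edges are handled by
#' reflect-padding with three filter lengths of samples, which suppresses the
#' startup transient of the recursion.
#'
#' @param x Numeric vector.
#' @param filt List with `b`, `a` coefficients as from [butter_design()].
#' @param npad Reflect-padding length in samples; the default, three filter
#'   lengths, suits broadband designs. Narrowband filters (impulse response
#'   ~ 1/bandwidth seconds) need proportionally longer padding.
#' @return Filtered vector, same length as `x`.
#' @keywords internal
zero_phase <- function(x, filt, npad = NULL) {
  b <- filt$b; a <- filt$a
  if (is.null(npad)) npad <- 3L * (max(length(b), length(a)) - 1L)
  n <- length(x)
  if (n <= npad + 1L) npad <- max(0L, n - 2L)
  if (npad > 0L) {
    headp <- 2 * x[1] - x[(npad + 1L):2L]
    tailp <- 2 * x[n] - x[(n - 1L):(n - npad)]
    xp <- c(headp, x, tailp)
  } else {
    xp <- x
  }
  y <- iir_pass(b, a, xp)
  y <- rev(iir_pass(b, a, rev(y)))
  if (npad > 0L) y <- y[(npad + 1L):(npad + n)]
  y
}

# Zero-phase filter applied to each row of a channels x samples matrix.
zero_phase_rows <- function(m, filt) {
  out <- m
  for (i in seq_len(nrow(m))) out[i, ] <- zero_phase(m[i, ], filt)
  out
}

#' Squared envelope via the analytic signal
#'
#' Instantaneous power of a (narrowband) signal, computed as the squared
#' magnitude of the FFT-based analytic signal.
#'
#' @param x Numeric vector.
#' @return Non-negative vector of instantaneous power, same length as `x`.
#' @keywords internal
analytic_power <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  z <- fft(X * h, inverse = TRUE) / n
  Mod(z)^2
}

# Ornstein-Uhlenbeck style AR(1) process with stationary sd `sigma` and
# correlation time `tau_s` seconds; used for envelopes and frequency jitter.
ou_process <- function(n, tau_s, sigma, fs) {
  rho <- exp(-1 / (tau_s * fs))
  eps <- rnorm(n, 0, sigma * sqrt(1 - rho^2))
  iir_filter_cpp(1, c(1, -rho), eps)
}

# Raised-cosine ramp from 0 to 1 over `ramp_n` samples.
raised_cosine <- function(ramp_n) {
  if (ramp_n <= 0L) return(numeric(0))
  0.5 * (1 - cos(pi * seq_len(ramp_n) / (ramp_n + 1)))
}
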