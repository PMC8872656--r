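.design_cache <- new.env(parent = emptyenv())

#' Design the Chebyshev type-I band-pass denoising filter
#'
#' The pulse signal of interest lives between the lowest plausible beat
#' rate and its first few harmonics, here 1-4 Hz; everything outside that
#' band (baseline drift from wrist movement, powerline pickup, broadband
#' sensor noise) is attenuated. `order` is the order of the realised
#' band-pass transfer function, so the low-pass prototype has order
#' `order / 2`.
#'
#' @param fs sampling rate, Hz.
#' @param low,high band edges, Hz.
#' @param order realised band-pass order (even, >= 2); default 6.
#' @param ripple_db passband ripple, dB; default 0.5.
#' @return An object of class `filter_spec` holding the transfer-function
#'   coefficients `b` (numerator) and `a` (denominator) together with the
#'   design parameters and the impulse settling length in samples.
#' @export
design_bandpass <- function(fs, low, high, order = 6, ripple_db = 0.5) {
  key <- paste(fs, low, high, order, ripple_db, sep = "|")
  if (!is.null(.design_cache[[key]])) return(.design_cache[[key]])
  if (!(0 < low && low < high && high < fs / 2))
    stop("filter design error: need 0 < low < high < fs/2")
  if (order < 2 || order %% 2 != 0)
    stop("filter design error: order must be even and >= 2")
  if (ripple_db <= 0) stop("filter design error: ripple must be > 0")
  flt <- signal::cheby1(order / 2, ripple_db, c(low, high) / (fs / 2),
                        type = "pass")
  b <- as.numeric(flt$b)
  a <- as.numeric(flt$a)
  poles <- polyroot(rev(a))
  if (max(Mod(poles)) >= 1)
    stop("filter design error: unstable design (pole on or outside unit circle)")
  spec <- structure(list(b = b, a = a, fs = fs, low = low, high = high,
                         order = order, ripple_db = ripple_db,
                         settle = impulse_settling_length(b, a)),
                    class = "filter_spec")
  .design_cache[[key]] <- spec
  spec
}

#' Frequency response of a designed filter
#'
#' Evaluates the single-pass transfer function H(f) on the unit circle.
#'
#' @param spec a `filter_spec`.
#' @param freq_hz frequencies at which to evaluate, Hz.
#' @return Complex response values, one per frequency.
#' @export
filter_response <- function(spec, freq_hz) {
  w <- 2 * pi * freq_hz / spec$fs
  z <- exp(-1i * w)
  num <- outer(z, seq_along(spec$b) - 1, `^`) %*% spec$b
  den <- outer(z, seq_along(spec$a) - 1, `^`) %*% spec$a
  as.vector(num / den)
}

# Number of samples after which the impulse response has decayed below
# 1e-4 of its peak magnitude; used to size reflection padding.
impulse_settling_length <- function(b, a, max_n = 20000L) {
  h <- signal::filter(b, a, c(1, numeric(max_n - 1L)))
  thr <- 1e-4 * max(abs(h))
  idx <- which(abs(h) > thr)
  if (length(idx)) max(idx) else max_n
}

# Zero-phase filtering of one numeric vector with mirror padding at both
# ends to suppress start-up transients.
zero_phase_filter <- function(x, spec) {
  n <- length(x)
  pad <- min(n - 1L, spec$settle)
  left <- 2 * x[1] - x[seq(pad + 1, 2)]
  right <- 2 * x[n] - x[seq(n - 1, n - pad)]
  xp <- c(left, x, right)
  y <- signal::filter(spec$b, spec$a, xp)
  y <- rev(signal::filter(spec$b, spec$a, rev(y)))
  y[seq(pad + 1, pad + n)]
}

#' Band-pass filter every channel of a recording
#'
#' Each channel is filtered independently. By default the filter is
#' applied forward and backward (zero phase), so fiducial timings are not
#' phase-distorted; the effective magnitude response is then |H(f)|^2.
#' The record must comfortably exceed the impulse settling length of the
#' design, otherwise edge transients would dominate.
#'
#' @param recording an [array_recording()].
#' @param spec a `filter_spec` from [design_bandpass()]; its sampling
#'   rate must match the recording.
#' @param zero_phase apply forward-backward (default) or single pass.
#' @return A filtered [array_recording()] of identical dimensions.
#' @export
apply_filter <- function(recording, spec, zero_phase = TRUE) {
  if (!identical(spec$fs, recording$fs))
    stop("filter fs (", spec$fs, ") does not match recording fs (",
         recording$fs, ")")
  n <- nrow(recording$samples)
  if (n <= 3 * spec$settle)
    stop(sprintf(
      "recording too short for this filter: %d samples <= 3 x settling length (%d)",
      n, spec$settle))
  out <- recording
  if (zero_phase) {
    out$samples <- apply(recording$samples, 2, zero_phase_filter, spec = spec)
  } else {
    out$samples <- apply(recording$samples, 2, function(x)
      as.numeric(signal::filter(spec$b, spec$a, x)))
  }
  colnames(out$samples) <- colnames(recording$samples)
  out
}
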