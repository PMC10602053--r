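#' Zero-phase Butterworth band-pass filter
#'
#' 4th-order Butterworth applied forward and backward (`signal::filtfilt`),
#' so filtering preserves the timing of troughs and peaks.
#'
#' @param x Numeric trace.
#' @param fs Sampling rate (Hz).
#' @param lo,hi Band edges (Hz); must satisfy `0 < lo < hi < fs/2`.
#' @param order Filter order (default 4).
#' @return Filtered trace.
#' @export
bandpass_filter <- function(x, fs, lo, hi, order = 4) {
  stopifnot(lo > 0, hi > lo, hi < fs / 2)
  bf <- signal::butter(order, c(lo, hi) / (fs / 2), type = "pass")
  signal::filtfilt(bf, x)
}

#' Zero-phase Butterworth low-pass filter
#' @inheritParams bandpass_filter
#' @param cutoff Cutoff frequency (Hz).
#' @export
lowpass_filter <- function(x, fs, cutoff, order = 4) {
  stopifnot(cutoff > 0, cutoff < fs / 2)
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  signal::filtfilt(bf, x)
}

#' Analytic signal via the frequency domain
#'
#' Returns the complex analytic signal `x + i * H(x)` (H = Hilbert transform),
#' constructed by zeroing negative frequencies of the DFT. `Arg()` of the
#' result is the instantaneous phase (0 at a peak of `x`, +-pi at a trough),
#' `Mod()` the instantaneous amplitude.
#'
#' @param x Real numeric trace.
#' @return Complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[2:(n / 2)] <- 2; h[n / 2 + 1] <- 1
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}
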