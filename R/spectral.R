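#' Standard EEG/EMG frequency bands
#'
#' Default band definitions: delta 0.5-4.5 Hz, theta 6-9.5 Hz, sigma
#' (spindle) 10-15 Hz, gamma 50-90 Hz, and the 5-100 Hz EMG integration band.
#'
#' @return Data.frame with columns `name`, `lo_hz`, `hi_hz`.
#' @export
band_definitions <- function() {
  data.frame(name = c("delta", "theta", "sigma", "gamma", "emg"),
             lo_hz = c(0.5, 6.0, 10, 50, 5),
             hi_hz = c(4.5, 9.5, 15, 90, 100))
}

band_def <- function(band) {
  if (is.character(band)) {
    defs <- band_definitions()
    i <- match(band, defs$name)
    if (is.na(i)) stop("unknown band name: ", band)
    return(list(lo = defs$lo_hz[i], hi = defs$hi_hz[i]))
  }
  list(lo = band[[1]], hi = band[[2]])
}

#' Welch power spectral density
#'
#' Averages periodograms over consecutive half-overlapping Hann-windowed
#' segments (default 2 s). Each segment is mean-removed before windowing (so
#' DC offsets do not leak into the delta band); there is no zero-padding.
#' One-sided density scaling: integrating the PSD over frequency recovers the
#' signal variance (Parseval), so units are uV^2/Hz for uV input.
#'
#' @param x Numeric trace (microvolts).
#' @param fs Sampling rate (Hz).
#' @param window_s Segment length in seconds (default 2).
#' @return List with `freq` (Hz) and `psd` (uV^2/Hz), class `psd`.
#' @export
welch_psd <- function(x, fs, window_s = 2) {
  nwin <- round(window_s * fs)
  if (length(x) < nwin)
    stop("trace shorter than one Welch window (", length(x), " < ", nwin, " samples)")
  hop <- nwin %/% 2
  starts <- seq(1, length(x) - nwin + 1, by = hop)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(nwin - 1)) / nwin)  # periodic Hann
  scale <- fs * sum(w^2)
  nf <- nwin %/% 2 + 1
  acc <- numeric(nf)
  for (s0 in starts) {
    seg <- x[s0:(s0 + nwin - 1)]
    seg <- (seg - mean(seg)) * w
    X <- fft(seg)[1:nf]
    p <- (Mod(X)^2) / scale
    p[2:(nf - 1)] <- 2 * p[2:(nf - 1)]   # one-sided (DC and Nyquist not doubled)
    acc <- acc + p
  }
  structure(list(freq = (0:(nf - 1)) * fs / nwin, psd = acc / length(starts)),
            class = "psd")
}

#' Band power by midpoint Riemann sum
#'
#' Approximates the area under the PSD over `[lo, hi]` by a midpoint Riemann
#' sum: bins whose center frequency falls inside the band (inclusive edges)
#' contribute `psd * df`.
#'
#' @param psd A `psd` object from [welch_psd()].
#' @param band Band name (see [band_definitions()]) or `c(lo, hi)` in Hz.
#' @return Scalar power (uV^2).
#' @export
band_power <- function(psd, band) {
  b <- band_def(band)
  if (b$lo < min(psd$freq) || b$hi > max(psd$freq))
    stop("band [", b$lo, ", ", b$hi, "] outside PSD frequency range")
  df <- psd$freq[2] - psd$freq[1]
  sel <- psd$freq >= b$lo & psd$freq <= b$hi
  sum(psd$psd[sel]) * df
}

#' EMG amplitude
#'
#' Square root of the EMG power integrated over 5-100 Hz (Welch PSD, midpoint
#' Riemann sum), in microvolts.
#'
#' @param emg EMG trace (uV).
#' @param fs Sampling rate (Hz).
#' @param window_s Welch segment length (default 2 s).
#' @param band Integration band, default `c(5, 100)` Hz.
#' @return Scalar amplitude (uV).
#' @export
emg_amplitude <- function(emg, fs, window_s = 2, band = c(5, 100)) {
  sqrt(band_power(welch_psd(emg, fs, window_s), band))
}

#' Sliding-window spectrogram
#'
#' One Welch PSD per sliding window (default 5 s windows, half-overlapping,
#' i.e. a 2.5 s hop; each window's PSD uses half-overlapping 2 s Hann
#' sub-segments). Incomplete trailing windows are dropped. Column times are
#' window centers.
#'
#' @param x Numeric trace.
#' @param fs Sampling rate (Hz).
#' @param window_s Window length (s), default 5.
#' @param step_s Hop between windows (s), default `window_s / 2`.
#' @param psd_window_s Welch sub-segment length (s), default 2.
#' @return List of class `spectrogram`: `times` (s, window centers), `freq`
#'   (Hz), `power` (matrix freq x time, uV^2/Hz), `window_s`, `step_s`.
#' @export
spectrogram <- function(x, fs, window_s = 5, step_s = window_s / 2,
                        psd_window_s = 2) {
  nwin <- round(window_s * fs)
  hop <- round(step_s * fs)
  if (length(x) < nwin) stop("trace shorter than one spectrogram window")
  starts <- seq(1, length(x) - nwin + 1, by = hop)
  cols <- lapply(starts, function(s0)
    welch_psd(x[s0:(s0 + nwin - 1)], fs, psd_window_s))
  structure(list(times = (starts - 1) / fs + window_s / 2,
                 freq = cols[[1]]$freq,
                 power = vapply(cols, function(p) p$psd,
                                numeric(length(cols[[1]]$freq))),
                 window_s = window_s, step_s = step_s),
            class = "spectrogram")
}

#' Band power time course from a spectrogram
#' @param sg A `spectrogram`.
#' @param band Band name or `c(lo, hi)` Hz.
#' @return Numeric vector, one power value (uV^2) per spectrogram column.
#' @export
band_timecourse <- function(sg, band) {
  b <- band_def(band)
  df <- sg$freq[2] - sg$freq[1]
  sel <- sg$freq >= b$lo & sg$freq <= b$hi
  colSums(sg$power[sel, , drop = FALSE]) * df
}

#' Laser-triggered normalized spectrogram and band time courses
#'
#' Normalizes each frequency component of the spectrogram by its temporal mean
#' across the recording excluding laser intervals, then averages trials
#' aligned at the laser onset. Band time courses are midpoint Riemann sums
#' over the normalized rows. Also returns per-trial mean band power during the
#' laser interval and the immediately preceding equal-length baseline.
#'
#' @param rec A `signal_recording`.
#' @param laser A `laser_train`.
#' @param pre_s,post_s Seconds before/after laser onset to include.
#' @param channel EEG channel used (default `"EEG_parietal"`).
#' @param bands Character vector of band names for the time courses.
#' @return List: `t` (s relative to onset), `freq`, `avg` (normalized
#'   trial-average, freq x time), `band_courses` (matrix time x band),
#'   `trial_band_means` (data.frame: trial, band, baseline, laser), `n_trials`.
#' @export
laser_triggered_spectrogram <- function(rec, laser, pre_s = 120, post_s = 240,
                                        channel = "EEG_parietal",
                                        bands = c("delta", "theta", "sigma", "gamma")) {
  x <- get_channel(rec, channel)
  sg <- spectrogram(x, rec$fs)
  half <- sg$window_s / 2
  col_laser <- vapply(sg$times, function(tc)
    any(in_laser(laser, c(tc - half, tc, tc + half - 1e-9))), logical(1))
  norm_mean <- rowMeans(sg$power[, !col_laser, drop = FALSE])
  norm_mean[norm_mean == 0] <- 1
  npow <- sg$power / norm_mean

  n_pre <- round(pre_s / sg$step_s)
  n_post <- round(post_s / sg$step_s)
  rel_idx <- seq(-n_pre, n_post - 1)
  trials <- list()
  for (on in laser$onsets) {
    j0 <- which.min(abs(sg$times - (on + half)))  # window starting at onset
    idx <- j0 + rel_idx
    if (idx[1] < 1 || idx[length(idx)] > ncol(npow)) next
    trials[[length(trials) + 1]] <- npow[, idx, drop = FALSE]
  }
  if (length(trials) == 0) stop("no complete laser trials inside the recording")
  avg <- Reduce(`+`, trials) / length(trials)
  t_rel <- rel_idx * sg$step_s

  df <- sg$freq[2] - sg$freq[1]
  course_of <- function(m, band) {
    b <- band_def(band)
    sel <- sg$freq >= b$lo & sg$freq <= b$hi
    colSums(m[sel, , drop = FALSE]) * df
  }
  band_courses <- vapply(bands, function(b) course_of(avg, b),
                         numeric(length(t_rel)))

  rows <- list()
  for (k in seq_along(trials)) {
    las <- t_rel >= 0 & t_rel < laser$duration_s[1]
    base <- t_rel >= -laser$duration_s[1] & t_rel < 0
    for (b in bands) {
      bc <- course_of(trials[[k]], b)
      rows[[length(rows) + 1]] <- data.frame(
        trial = k, band = b,
        baseline = mean(bc[base]), laser = mean(bc[las]))
    }
  }
  list(t = t_rel, freq = sg$freq, avg = avg, band_courses = band_courses,
       trial_band_means = do.call(rbind, rows), n_trials = length(trials))
}
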