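# Phasic theta event detection inside REM sleep: troughs of the 5-12 Hz
# filtered EEG from the Hilbert phase, inter-trough intervals smoothed with an
# 11-element box filter, then a four-gate criterion (sub-10th-percentile run,
# >= 900 ms, minimum below the 5th percentile, amplitude above the REM mean).

#' Theta troughs and instantaneous amplitude of one REM episode
#'
#' Band-passes the EEG to 5-12 Hz (4th-order zero-phase Butterworth), forms
#' the analytic signal, and identifies troughs as local minima of the wrapped
#' instantaneous phase with value < -3 rad (the phase is 0 at a waveform peak
#' and +-pi at a trough), at most one per cycle.
#'
#' @param x Parietal EEG trace of one REM episode (uV).
#' @param fs Sampling rate (Hz).
#' @param band Filter band, default `c(5, 12)` Hz.
#' @return List: `trough_idx` (sample indices), `trough_s` (seconds from trace
#'   start), `amplitude` (instantaneous amplitude per sample), `phase`.
#' @export
theta_troughs <- function(x, fs, band = c(5, 12)) {
  if (length(x) < 3 * fs / band[1])
    stop("episode shorter than the filter warm-up")
  xf <- bandpass_filter(x, fs, band[1], band[2])
  # a trace with no in-band energy (e.g. DC) leaves only filter edge ringing
  if (sd(x) < .Machine$double.eps || sd(xf) <= 1e-9 * sd(x)) {
    return(list(trough_idx = integer(0), trough_s = numeric(0),
                amplitude = rep(0, length(x)), phase = rep(0, length(x))))
  }
  an <- analytic_signal(xf)
  ph <- Arg(an)
  n <- length(ph)
  is_min <- c(FALSE, ph[2:(n - 1)] < ph[1:(n - 2)] &
                     ph[2:(n - 1)] < ph[3:n], FALSE)
  idx <- which(is_min & ph < -3)
  # one trough per cycle: enforce a minimum separation of half the fastest period
  if (length(idx) > 1) {
    min_gap <- round(0.5 * fs / band[2])
    keep <- idx[1]
    for (i in idx[-1]) if (i - keep[length(keep)] >= min_gap) keep <- c(keep, i)
    idx <- keep
  }
  list(trough_idx = idx, trough_s = (idx - 1) / fs,
       amplitude = Mod(an), phase = ph)
}

# 11-element box filter with shrinking windows at the edges
smooth_box <- function(x, width = 11) {
  half <- width %/% 2
  n <- length(x)
  vapply(seq_len(n), function(i)
    mean(x[max(1, i - half):min(n, i + half)]), numeric(1))
}

#' Detect phasic theta events in REM episodes
#'
#' For each episode: trough times and inter-trough intervals (ITIs), smoothed
#' per episode with an 11-element box filter (shrinking at the edges). A
#' candidate is a maximal run of smoothed ITIs strictly below the 10th
#' percentile spanning at least `min_duration_s` from first to last trough.
#' It becomes an event if its minimum smoothed ITI is below the 5th percentile
#' and its mean instantaneous theta amplitude exceeds the mean amplitude over
#' all REM sleep. Percentiles (linear interpolation) and the mean amplitude
#' are pooled over the supplied episodes - pass the non-laser episodes when
#' computing thresholds, or reuse `thresholds` across conditions.
#'
#' @param traces List of numeric EEG traces, one per REM episode.
#' @param fs Sampling rate (Hz).
#' @param episode_start_s Start time (s) of each episode in the recording
#'   (defaults to 0s; event times are episode-relative then).
#' @param thresholds Optional list from a previous run (`pct10_s`, `pct5_s`,
#'   `mean_rem_amp`); computed from `traces` when omitted.
#' @param min_duration_s Minimum event duration, default 0.9 s.
#' @param band Theta filter band (Hz).
#' @return List: `events` (data.frame start_s, end_s, duration_s,
#'   min_smoothed_iti_s, mean_theta_amp, episode_id), `thresholds`.
#' @export
detect_phasic <- function(traces, fs, episode_start_s = rep(0, length(traces)),
                          thresholds = NULL, min_duration_s = 0.9,
                          band = c(5, 12)) {
  if (length(traces) == 0) stop("need at least one REM episode")
  per_ep <- vector("list", length(traces))
  for (e in seq_along(traces)) {
    tr <- tryCatch(theta_troughs(traces[[e]], fs, band),
                   error = function(err) NULL)
    if (is.null(tr) || length(tr$trough_idx) < 12) {
      if (!is.null(tr)) warning("episode ", e, " has fewer than 11 inter-trough intervals; skipped")
      else warning("episode ", e, " shorter than filter warm-up; skipped")
      next
    }
    iti <- diff(tr$trough_s)
    per_ep[[e]] <- list(troughs = tr$trough_s, iti = iti,
                        siti = smooth_box(iti, 11), amp = tr$amplitude)
  }
  have <- !vapply(per_ep, is.null, logical(1))
  if (!any(have)) {
    warning("no episode yielded enough troughs; empty result")
    return(list(events = empty_phasic_table(), thresholds = thresholds))
  }
  if (is.null(thresholds)) {
    all_siti <- unlist(lapply(per_ep[have], `[[`, "siti"))
    all_amp <- unlist(lapply(per_ep[have], `[[`, "amp"))
    thresholds <- list(pct10_s = quantile(all_siti, 0.10, names = FALSE),
                       pct5_s = quantile(all_siti, 0.05, names = FALSE),
                       mean_rem_amp = mean(all_amp))
  }
  out <- list()
  for (e in which(have)) {
    pe <- per_ep[[e]]
    below <- pe$siti < thresholds$pct10_s
    r <- rle(below)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      i <- starts[k]; j <- ends[k]
      t0 <- pe$troughs[i]; t1 <- pe$troughs[j + 1]
      if (t1 - t0 < min_duration_s) next
      mn <- min(pe$siti[i:j])
      if (mn >= thresholds$pct5_s) next
      samp <- (round(t0 * fs) + 1):(round(t1 * fs) + 1)
      m_amp <- mean(pe$amp[samp])
      if (m_amp <= thresholds$mean_rem_amp) next
      out[[length(out) + 1]] <- data.frame(
        start_s = episode_start_s[e] + t0, end_s = episode_start_s[e] + t1,
        duration_s = t1 - t0, min_smoothed_iti_s = mn,
        mean_theta_amp = m_amp, episode_id = e)
    }
  }
  events <- if (length(out) > 0) do.call(rbind, out) else empty_phasic_table()
  list(events = events, thresholds = thresholds)
}

empty_phasic_table <- function() {
  data.frame(start_s = numeric(0), end_s = numeric(0), duration_s = numeric(0),
             min_smoothed_iti_s = numeric(0), mean_theta_amp = numeric(0),
             episode_id = integer(0))
}

#' Detect phasic theta events directly from a recording and hypnogram
#'
#' Convenience wrapper: segments REM episodes, detects events, and returns
#' them in recording time. Thresholds are computed from episodes not
#' overlapping the laser when a `laser_train` is given.
#'
#' @param rec A `signal_recording`.
#' @param h The `hypnogram`.
#' @param laser Optional `laser_train`.
#' @param channel EEG channel, default parietal.
#' @param ... Passed to [detect_phasic()].
#' @return As [detect_phasic()], plus `rem_episodes`.
#' @export
phasic_from_recording <- function(rec, h, laser = NULL,
                                  channel = "EEG_parietal", ...) {
  eps <- episodes(h, "R", bridge_microarousal_s = 0)
  if (nrow(eps) == 0) stop("hypnogram contains no REM episodes")
  x <- get_channel(rec, channel)
  traces <- lapply(seq_len(nrow(eps)), function(i)
    channel_segment(rec, channel, eps$start_s[i], eps$end_s[i]))
  thr <- NULL
  if (!is.null(laser)) {
    grid <- lapply(seq_len(nrow(eps)), function(i)
      seq(eps$start_s[i], eps$end_s[i], by = 1))
    off <- which(!vapply(grid, function(g) any(in_laser(laser, g)), logical(1)))
    if (length(off) > 0) {
      thr <- detect_phasic(traces[off], rec$fs,
                           episode_start_s = eps$start_s[off], ...)$thresholds
    }
  }
  res <- detect_phasic(traces, rec$fs, episode_start_s = eps$start_s,
                       thresholds = thr, ...)
  res$rem_episodes <- eps
  res
}

#' Phasic event frequency and tonic/phasic spectral contrast
#'
#' Event frequency is events per minute of REM (split into laser-on / laser-off
#' episode sets when a laser train is given: an episode counts as ON if it
#' overlaps any laser interval). The event PSD includes only events at least
#' as long as the 2 s Welch window; tonic REM is all remaining REM time.
#'
#' @param events Phasic event table from [detect_phasic()].
#' @param rem_eps REM episode table from [episodes()].
#' @param rec Optional `signal_recording` for the PSD contrast.
#' @param laser Optional `laser_train` for the ON/OFF split.
#' @param channel EEG channel.
#' @return List: `events_per_min` (overall and, with laser, `on`/`off`),
#'   `psd_phasic`, `psd_tonic` (each a `psd` or NULL), `peak_freq_hz`,
#'   `theta_power` (named phasic/tonic).
#' @export
phasic_metrics <- function(events, rem_eps, rec = NULL, laser = NULL,
                           channel = "EEG_parietal") {
  total_min <- sum(rem_eps$duration_s) / 60
  out <- list(events_per_min = nrow(events) / total_min)
  if (!is.null(laser)) {
    on_ep <- vapply(seq_len(nrow(rem_eps)), function(i)
      any(in_laser(laser, seq(rem_eps$start_s[i], rem_eps$end_s[i], by = 1))),
      logical(1))
    for (grp in c(TRUE, FALSE)) {
      ids <- rem_eps$episode_id[on_ep == grp]
      mins <- sum(rem_eps$duration_s[on_ep == grp]) / 60
      cnt <- sum(events$episode_id %in% ids)
      out[[if (grp) "events_per_min_on" else "events_per_min_off"]] <-
        if (mins > 0) cnt / mins else NA_real_
    }
  }
  if (!is.null(rec)) {
    long <- events[events$duration_s >= 2, , drop = FALSE]
    avg_psd <- function(segs) {
      segs <- segs[vapply(segs, length, integer(1)) >= 2 * rec$fs]
      if (length(segs) == 0) return(NULL)
      ps <- lapply(segs, welch_psd, fs = rec$fs, window_s = 2)
      structure(list(freq = ps[[1]]$freq,
                     psd = Reduce(`+`, lapply(ps, `[[`, "psd")) / length(ps)),
                class = "psd")
    }
    ph_segs <- lapply(seq_len(nrow(long)), function(i)
      channel_segment(rec, channel, long$start_s[i], long$end_s[i]))
    ton_segs <- list()
    for (i in seq_len(nrow(rem_eps))) {
      bounds <- sort(c(rem_eps$start_s[i], rem_eps$end_s[i],
                       pmax(pmin(events$start_s[events$episode_id == i],
                                 rem_eps$end_s[i]), rem_eps$start_s[i]),
                       pmax(pmin(events$end_s[events$episode_id == i],
                                 rem_eps$end_s[i]), rem_eps$start_s[i])))
      for (k in seq_len(length(bounds) - 1)) {
        mid <- (bounds[k] + bounds[k + 1]) / 2
        inside_event <- any(events$start_s <= mid & events$end_s > mid)
        if (!inside_event && bounds[k + 1] - bounds[k] >= 2)
          ton_segs[[length(ton_segs) + 1]] <-
            channel_segment(rec, channel, bounds[k], bounds[k + 1])
      }
    }
    out$psd_phasic <- avg_psd(ph_segs)
    out$psd_tonic <- avg_psd(ton_segs)
    pk <- function(p) if (is.null(p)) NA_real_ else p$freq[which.max(p$psd)]
    tp <- function(p) if (is.null(p)) NA_real_ else band_power(p, c(5, 12))
    out$peak_freq_hz <- c(phasic = pk(out$psd_phasic), tonic = pk(out$psd_tonic))
    out$theta_power <- c(phasic = tp(out$psd_phasic), tonic = tp(out$psd_tonic))
  }
  out
}
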