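# Heart-rate extraction from the nuchal EMG during REM sleep. R-waves appear
# as sharp negative deflections; an episode is usable only when a threshold
# exists that separates them from background noise, diagnosed from the shape
# of the peak-count-vs-threshold curve.

#' Peak-count threshold curve of a REM episode's EMG
#'
#' Band-passes the EMG to 10-100 Hz, then for thresholds rising from -100 to
#' 0 uV (1 uV grid) counts the negative peaks (local minima) below each
#' threshold, enforcing a refractory gap between counted peaks (default 50 ms,
#' the 1200 bpm physiological ceiling for a mouse). Counts are non-decreasing
#' in the threshold by construction.
#'
#' @param emg EMG trace of one REM episode (uV).
#' @param fs Sampling rate (Hz).
#' @param thresholds Threshold grid (uV), default `seq(-100, 0, by = 1)`.
#' @param refractory_s Minimum separation between counted peaks (s).
#' @return List of class `threshold_curve`: `thresholds`, `counts`,
#'   `peak_values`, `peak_times_s`, `fs`, `refractory_s`.
#' @export
threshold_curve <- function(emg, fs, thresholds = seq(-100, 0, by = 1),
                            refractory_s = 0.05) {
  xf <- bandpass_filter(emg, fs, 10, 100)
  n <- length(xf)
  is_min <- c(FALSE, xf[2:(n - 1)] < xf[1:(n - 2)] &
                     xf[2:(n - 1)] <= xf[3:n], FALSE)
  pk_i <- which(is_min & xf < 0)
  pk_v <- xf[pk_i]
  gap <- refractory_s * fs
  counts <- vapply(thresholds, function(thr) {
    sel <- pk_i[pk_v < thr]
    if (length(sel) == 0) return(0L)
    cnt <- 1L; last <- sel[1]
    for (i in sel[-1]) if (i - last >= gap) { cnt <- cnt + 1L; last <- i }
    cnt
  }, integer(1))
  counts <- cummax(counts)
  structure(list(thresholds = thresholds, counts = counts,
                 peak_values = pk_v, peak_times_s = (pk_i - 1) / fs,
                 fs = fs, refractory_s = refractory_s),
            class = "threshold_curve")
}

#' Select an R-wave detection threshold from a threshold curve
#'
#' If R-waves stand clear of the noise, the count curve rises to a plateau
#' (all R-waves counted) and only rises again once the threshold reaches the
#' noise peaks; the episode is accepted iff such an inflection exists within
#' (-60, 0) uV. Operationally: the counts are smoothed with a 5-point moving
#' average; the inflection is the first concave-to-convex sign change of the
#' second difference inside the range, and requires plateau evidence (a
#' nonzero count at -60 uV, i.e. R-wave-sized peaks already counted, with the
#' candidate's count at least half of it).
#'
#' @param curve A `threshold_curve`.
#' @param range Acceptance range for the inflection (uV), default `c(-60, 0)`.
#' @param smooth_n Moving-average width for the counts (default 5).
#' @return List: `accepted` (logical), `threshold_uV` (NA when rejected),
#'   `reason` (character, when rejected).
#' @export
select_threshold <- function(curve, range = c(-60, 0), smooth_n = 5) {
  cs <- smooth_box(curve$counts, smooth_n)
  d2 <- c(NA, diff(cs, differences = 2), NA)
  i60 <- which.min(abs(curve$thresholds - range[1]))
  if (cs[i60] <= 0) {
    return(list(accepted = FALSE, threshold_uV = NA_real_,
                reason = "no peaks counted at the lower range edge (no plateau)"))
  }
  in_range <- which(curve$thresholds > range[1] & curve$thresholds < range[2])
  in_range <- in_range[in_range >= 3 & in_range <= length(cs) - 1]
  for (i in in_range) {
    if (!is.na(d2[i]) && !is.na(d2[i - 1]) && d2[i] > 0 && d2[i - 1] <= 0 &&
        cs[i] >= 0.5 * cs[i60]) {
      return(list(accepted = TRUE, threshold_uV = curve$thresholds[i],
                  reason = NA_character_))
    }
  }
  list(accepted = FALSE, threshold_uV = NA_real_,
       reason = "no concave-to-convex inflection in range")
}

#' Detect R-waves and heart rate in REM episodes
#'
#' Per REM episode: builds the threshold curve, applies the inflection
#' criterion, and (if accepted) detects R-waves as the negative peaks below
#' the selected threshold with the refractory gap. The instantaneous rate of
#' each inter-beat interval is 60 / interval; intervals whose midpoint lies
#' inside a phasic theta event are scored phasic, the rest tonic.
#'
#' @param emg Full-recording EMG trace (uV).
#' @param fs Sampling rate (Hz).
#' @param rem_eps REM episode table from [episodes()].
#' @param phasic Optional phasic event table (`start_s`, `end_s`) in recording
#'   time.
#' @param cap_bpm Physiological rate ceiling; intervals implying more are
#'   discarded (default 1200).
#' @param ... Passed to [threshold_curve()] / [select_threshold()].
#' @return List: `episodes` (per-episode: episode_id, accepted, threshold_uV,
#'   n_beats, mean_bpm, mean_bpm_tonic, mean_bpm_phasic), `beats` (data.frame
#'   t_s, bpm, phasic, episode_id), `mean_bpm_tonic`, `mean_bpm_phasic`.
#' @export
heart_rate <- function(emg, fs, rem_eps, phasic = NULL, cap_bpm = 1200, ...) {
  ep_rows <- list(); beat_rows <- list()
  for (i in seq_len(nrow(rem_eps))) {
    i0 <- floor(rem_eps$start_s[i] * fs) + 1
    i1 <- min(length(emg), ceiling(rem_eps$end_s[i] * fs))
    seg <- emg[i0:i1]
    curve <- threshold_curve(seg, fs, ...)
    sel <- select_threshold(curve)
    row <- data.frame(episode_id = rem_eps$episode_id[i], accepted = sel$accepted,
                      threshold_uV = sel$threshold_uV, n_beats = 0L,
                      mean_bpm = NA_real_, mean_bpm_tonic = NA_real_,
                      mean_bpm_phasic = NA_real_)
    if (sel$accepted) {
      keep <- curve$peak_times_s[curve$peak_values < sel$threshold_uV]
      if (length(keep) > 1) {
        r_times <- keep[1]
        for (t in keep[-1]) if (t - r_times[length(r_times)] >= curve$refractory_s)
          r_times <- c(r_times, t)
        r_abs <- r_times + rem_eps$start_s[i]
        ibi <- diff(r_abs)
        bpm <- 60 / ibi
        ok <- bpm <= cap_bpm
        mid <- (r_abs[-1] + r_abs[-length(r_abs)]) / 2
        is_ph <- rep(FALSE, length(mid))
        if (!is.null(phasic) && nrow(phasic) > 0) {
          for (k in seq_len(nrow(phasic)))
            is_ph <- is_ph | (mid >= phasic$start_s[k] & mid < phasic$end_s[k])
        }
        row$n_beats <- length(r_abs)
        row$mean_bpm <- mean(bpm[ok])
        row$mean_bpm_tonic <- if (any(ok & !is_ph)) mean(bpm[ok & !is_ph]) else NA_real_
        row$mean_bpm_phasic <- if (any(ok & is_ph)) mean(bpm[ok & is_ph]) else NA_real_
        beat_rows[[length(beat_rows) + 1]] <-
          data.frame(t_s = mid[ok], bpm = bpm[ok], phasic = is_ph[ok],
                     episode_id = rem_eps$episode_id[i])
      }
    }
    ep_rows[[length(ep_rows) + 1]] <- row
  }
  eps <- do.call(rbind, ep_rows)
  beats <- if (length(beat_rows) > 0) do.call(rbind, beat_rows)
           else data.frame(t_s = numeric(0), bpm = numeric(0),
                           phasic = logical(0), episode_id = integer(0))
  if (!any(eps$accepted)) warning("all REM episodes rejected: no isolatable R-waves")
  list(episodes = eps, beats = beats,
       mean_bpm_tonic = if (any(!beats$phasic)) mean(beats$bpm[!beats$phasic]) else NA_real_,
       mean_bpm_phasic = if (any(beats$phasic)) mean(beats$bpm[beats$phasic]) else NA_real_)
}
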