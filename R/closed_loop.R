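# Closed-loop (online) REM detection: threshold calibration from a scored
# recording, then streaming detection from causal 2.5 s feature steps.

#' Causal spectral feature stream for online REM detection
#'
#' Every 2.5 s step computes, from the trailing 5 s of data only, the delta
#' power, theta power, theta/delta ratio (parietal EEG) and EMG amplitude
#' (5-100 Hz), using the same Welch settings as the offline spectrogram. The
#' decision timestamp of each row is the window end, so each row depends only
#' on samples up to that time.
#'
#' @param rec A `signal_recording` with EEG and EMG channels.
#' @param channel EEG channel used for the ratio (default parietal).
#' @return Data.frame: `t_s` (decision time = window end), `delta`, `theta`,
#'   `thdelta`, `emg_amp`.
#' @export
closed_loop_features <- function(rec, channel = "EEG_parietal") {
  sg <- spectrogram(get_channel(rec, channel), rec$fs)
  sge <- spectrogram(get_channel(rec, "EMG"), rec$fs)
  delta <- band_timecourse(sg, "delta")
  theta <- band_timecourse(sg, "theta")
  emg_amp <- sqrt(band_timecourse(sge, "emg"))
  data.frame(t_s = sg$times + sg$window_s / 2,
             delta = delta, theta = theta, thdelta = theta / delta,
             emg_amp = emg_amp)
}

#' Calibrate closed-loop REM-detection thresholds
#'
#' The online decision rule (delta and EMG below threshold, theta/delta above
#' a hard threshold to enter; below a soft threshold or EMG above threshold to
#' exit) needs four thresholds, derived here from a previously scored
#' recording of the same animal: `delta_max` = mean NREM delta power;
#' `emg_max` = mean NREM EMG amplitude + k1 SD; `thdelta_hard` = mean REM
#' theta/delta - k2 SD, floored at the NREM 95th percentile of theta/delta;
#' `thdelta_soft` = f x hard. The theta/delta ratio is right-skewed, so the
#' default k2 = 1.2 places the hard threshold near the lower tail of the REM
#' distribution (the NREM floor still guards against false triggers); smaller
#' k2 values delay onset detection.
#'
#' @param rec A scored `signal_recording`.
#' @param h The matching `hypnogram` (must contain W, N and R epochs).
#' @param k1,k2,f Calibration constants (defaults 1, 1.2, 0.6).
#' @param channel EEG channel.
#' @return List of class `closed_loop_thresholds`.
#' @export
calibrate_thresholds <- function(rec, h, k1 = 1, k2 = 1.2, f = 0.6,
                                 channel = "EEG_parietal") {
  stopifnot(f > 0, f <= 1)
  feats <- closed_loop_features(rec, channel)
  st <- state_at(h, feats$t_s - h$epoch_s / 2)  # state of the last epoch in window
  for (s in c("W", "N", "R")) {
    if (!any(st == s, na.rm = TRUE))
      stop("calibration data contain no ", c(W = "wake", N = "NREM", R = "REM")[s],
           " (", s, ") epochs")
  }
  nrem <- which(st == "N"); rem <- which(st == "R")
  delta_max <- mean(feats$delta[nrem])
  emg_max <- mean(feats$emg_amp[nrem]) + k1 * sd(feats$emg_amp[nrem])
  hard <- mean(feats$thdelta[rem]) - k2 * sd(feats$thdelta[rem])
  hard <- max(hard, quantile(feats$thdelta[nrem], 0.95, names = FALSE))
  structure(list(delta_max = delta_max, emg_max = emg_max,
                 thdelta_hard = hard, thdelta_soft = f * hard,
                 k1 = k1, k2 = k2, f = f),
            class = "closed_loop_thresholds")
}

#' Streaming REM detection with hysteresis
#'
#' Walks the causal feature stream in time order. Detection onset: delta power
#' and EMG amplitude below their thresholds and theta/delta above the hard
#' threshold. Detection offset: theta/delta below the soft threshold or EMG
#' above its threshold. Between onset and offset the detector stays on
#' (hysteresis), so theta/delta dipping between soft and hard never
#' re-triggers.
#'
#' @param rec A `signal_recording`, or a feature data.frame from
#'   [closed_loop_features()].
#' @param thresholds A `closed_loop_thresholds`.
#' @param channel EEG channel (when `rec` is a recording).
#' @return Data.frame of detections: `onset_s`, `offset_s` (offset `NA` if
#'   still on at the end of the recording).
#' @export
detect_rem_stream <- function(rec, thresholds, channel = "EEG_parietal") {
  feats <- if (is.data.frame(rec)) rec else closed_loop_features(rec, channel)
  on <- FALSE
  onsets <- numeric(0); offsets <- numeric(0)
  for (i in seq_len(nrow(feats))) {
    if (!on) {
      if (feats$delta[i] < thresholds$delta_max &&
          feats$emg_amp[i] < thresholds$emg_max &&
          feats$thdelta[i] > thresholds$thdelta_hard) {
        on <- TRUE
        onsets <- c(onsets, feats$t_s[i])
      }
    } else {
      if (feats$thdelta[i] < thresholds$thdelta_soft ||
          feats$emg_amp[i] > thresholds$emg_max) {
        on <- FALSE
        offsets <- c(offsets, feats$t_s[i])
      }
    }
  }
  if (on) offsets <- c(offsets, NA_real_)
  data.frame(onset_s = onsets, offset_s = offsets)
}

#' Validate online detections against a scored hypnogram
#'
#' Per true REM bout: whether any detection onset fell inside it, and the
#' latency from bout onset to the first detection onset.
#'
#' @param detections Data.frame from [detect_rem_stream()].
#' @param h The scored `hypnogram`.
#' @param min_bout_s Only bouts at least this long are scored (default 0).
#' @return List: `bouts` (per-bout table: start_s, end_s, detected,
#'   latency_s), `hit_rate`, `median_latency_s`, `n_false_onsets` (detection
#'   onsets outside any REM bout).
#' @export
validate_rem_detection <- function(detections, h, min_bout_s = 0) {
  bouts <- episodes(h, "R", bridge_microarousal_s = 0)
  bouts <- bouts[bouts$duration_s >= min_bout_s, , drop = FALSE]
  det <- lat <- rep(NA_real_, nrow(bouts))
  for (i in seq_len(nrow(bouts))) {
    hit <- detections$onset_s[detections$onset_s >= bouts$start_s[i] &
                              detections$onset_s < bouts$end_s[i]]
    det[i] <- length(hit) > 0
    if (length(hit) > 0) lat[i] <- min(hit) - bouts$start_s[i]
  }
  in_rem <- state_at(h, detections$onset_s - 1e-9) == "R"
  list(bouts = data.frame(start_s = bouts$start_s, end_s = bouts$end_s,
                          duration_s = bouts$duration_s,
                          detected = as.logical(det), latency_s = lat),
       hit_rate = mean(det),
       median_latency_s = median(lat, na.rm = TRUE),
       n_false_onsets = sum(!in_rem, na.rm = TRUE))
}

#' Seeded coin flip for 50% closed-loop episode selection
#'
#' Utility mirroring the protocol of stimulating a random half of detected
#' REM episodes.
#'
#' @param n Number of episodes.
#' @param seed Integer seed.
#' @return Logical vector (TRUE = laser on).
#' @export
laser_on_coinflip <- function(n, seed) {
  with_stage_seed(seed, "coinflip", runif(n) < 0.5)
}
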