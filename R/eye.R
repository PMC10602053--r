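# Pupil localization and rapid-eye-movement (EM) detection during REM sleep.

#' Locate the pupil in a grayscale frame
#'
#' Inverts the frame (pupil dark -> bright), smooths with a small Gaussian,
#' binarizes at `threshold`, and takes the centroid of the largest connected
#' component. Components below `min_area` pixels (blink/occlusion) are
#' invalid.
#'
#' @param frame Numeric matrix in [0, 1] (rows = x, cols = y).
#' @param threshold Binarization threshold on the inverted, smoothed frame.
#' @param smooth_sigma Gaussian sigma in px (default 2).
#' @param min_area Minimum component area in px (default 20).
#' @return Named numeric `c(x, y)` centroid, or `c(NA, NA)` when invalid.
#' @export
pupil_center <- function(frame, threshold = 0.5, smooth_sigma = 2,
                         min_area = 20) {
  inv <- max(frame) - frame
  sm <- EBImage::gblur(inv, sigma = smooth_sigma)
  bw <- sm > threshold
  if (!any(bw)) return(c(x = NA_real_, y = NA_real_))
  lab <- EBImage::bwlabel(bw)
  areas <- tabulate(lab[lab > 0])
  big <- which.max(areas)
  if (areas[big] < min_area) return(c(x = NA_real_, y = NA_real_))
  sel <- which(lab == big, arr.ind = TRUE)
  c(x = mean(sel[, 1]), y = mean(sel[, 2]))
}

#' Pupil trace from a frame stack
#'
#' @param frames Array `x_px x y_px x n_frames`.
#' @param fs Camera frame rate (Hz), default 30.
#' @param ... Passed to [pupil_center()].
#' @return Data.frame `t_s`, `x_px`, `y_px`, `valid`.
#' @export
pupil_trace_from_frames <- function(frames, fs = 30, ...) {
  n <- dim(frames)[3]
  xy <- t(vapply(seq_len(n), function(i) pupil_center(frames[, , i], ...),
                 numeric(2)))
  data.frame(t_s = (seq_len(n) - 1) / fs, x_px = xy[, 1], y_px = xy[, 2],
             valid = !is.na(xy[, 1]))
}

#' Detect rapid eye movements from a pupil trace
#'
#' Speed is the Euclidean displacement between successive frames;
#' acceleration is the frame-to-frame change in speed (px/frame^2, on the
#' camera clock). The detection threshold is 2 standard deviations of the
#' acceleration computed over all REM samples of the recording, so detections
#' are invariant to rescaling the trace. Events are positive local maxima of
#' the acceleration above threshold, separated by at least `refractory_s`,
#' inside REM only. Samples flagged invalid (blinks) are excluded from the SD
#' and cannot carry events.
#'
#' @param trace Data.frame `t_s`, `x_px`, `y_px`, `valid` (see
#'   [simulate_pupil()] / [pupil_trace_from_frames()]).
#' @param h The scored `hypnogram`.
#' @param k_sd Threshold multiple of the REM acceleration SD (default 2).
#' @param refractory_s Minimum separation between events (default 0.1 s,
#'   below the 250 ms burst-grouping gap).
#' @return List: `events` (data.frame t_s, accel), `sd_rem` (the SD used),
#'   `rem_minutes`.
#' @export
detect_ems <- function(trace, h, k_sd = 2, refractory_s = 0.1) {
  n <- nrow(trace)
  speed <- sqrt(diff(trace$x_px)^2 + diff(trace$y_px)^2)
  sp_valid <- trace$valid[-n] & trace$valid[-1]
  accel <- diff(speed)                       # index j -> frame j + 2
  ac_valid <- sp_valid[-length(sp_valid)] & sp_valid[-1]
  t_ac <- trace$t_s[seq_along(accel) + 2]
  st <- state_at(h, t_ac)
  rem <- !is.na(st) & st == "R"
  if (!any(rem)) {
    warning("no REM sleep in hypnogram; no EM events")
    return(list(events = data.frame(t_s = numeric(0), accel = numeric(0)),
                sd_rem = NA_real_, rem_minutes = 0))
  }
  sdr <- sd(accel[rem & ac_valid])
  m <- length(accel)
  is_max <- c(FALSE, accel[2:(m - 1)] > accel[1:(m - 2)] &
                     accel[2:(m - 1)] >= accel[3:m], FALSE)
  cand <- which(is_max & accel > k_sd * sdr & rem & ac_valid)
  if (length(cand) > 1) {
    keep <- cand[1]
    dt <- trace$t_s[2] - trace$t_s[1]
    for (i in cand[-1]) if ((i - keep[length(keep)]) * dt >= refractory_s)
      keep <- c(keep, i)
    cand <- keep
  }
  rem_min <- sum(episodes(h, "R", bridge_microarousal_s = 0)$duration_s) / 60
  list(events = data.frame(t_s = t_ac[cand], accel = accel[cand]),
       sd_rem = sdr, rem_minutes = rem_min)
}

#' Group rapid eye movements into bursts
#'
#' Transitively groups events whose consecutive gaps are strictly below
#' `gap_s` (default 250 ms); groups with a single event are not bursts.
#' Also reports EM and burst frequencies per minute of REM and, per REM
#' episode, the latency from episode onset to the first EM.
#'
#' @param events Event data.frame (`t_s`) from [detect_ems()].
#' @param rem_eps Optional REM episode table from [episodes()] for the
#'   frequency and latency summaries.
#' @param gap_s Burst-grouping gap (s), strict inequality.
#' @return List: `events` (with `burst_id`, NA for singletons), `n_bursts`,
#'   `em_per_min`, `bursts_per_min`, `latency` (per-episode data.frame).
#' @export
group_bursts <- function(events, rem_eps = NULL, gap_s = 0.25) {
  t <- sort(events$t_s)
  grp <- integer(length(t))
  if (length(t) > 0) {
    grp[1] <- 1
    for (i in seq_along(t)[-1])
      grp[i] <- if (t[i] - t[i - 1] < gap_s) grp[i - 1] else grp[i - 1] + 1
  }
  sizes <- tabulate(grp)
  burst_ids <- which(sizes >= 2)
  burst_id <- ifelse(grp %in% burst_ids, match(grp, burst_ids), NA_integer_)
  out <- list(events = data.frame(t_s = t, burst_id = burst_id),
              n_bursts = length(burst_ids))
  if (!is.null(rem_eps)) {
    mins <- sum(rem_eps$duration_s) / 60
    out$em_per_min <- length(t) / mins
    out$bursts_per_min <- length(burst_ids) / mins
    out$latency <- data.frame(
      episode_id = rem_eps$episode_id,
      latency_s = vapply(seq_len(nrow(rem_eps)), function(i) {
        inb <- t[t >= rem_eps$start_s[i] & t < rem_eps$end_s[i]]
        if (length(inb) == 0) NA_real_ else min(inb) - rem_eps$start_s[i]
      }, numeric(1)))
  }
  out
}
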