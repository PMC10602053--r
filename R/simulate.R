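# Synthetic-data generator. Emulates the structure of a rodent sleep-physiology
# recording (semi-Markov hypnogram, state-conditioned EEG spectra with phasic
# theta accelerations, EMG tone with embedded ECG R-waves, saccadic pupil
# traces, calcium movies with state-tuned cell subclasses) together with
# ground-truth ledgers, so every analysis stage can be validated without raw
# data. Spectra are stylized, not biophysical: validation is parameter
# recovery, not waveform realism.

#' Simulation configuration
#'
#' Mouse-realistic defaults: tonic theta 7.5 Hz accelerating to 9 Hz with
#' amplitude x1.5 during 1.5 s phasic events (3 per min of REM); heart rate
#' 600 bpm rising to 660 bpm during phasic events with -80 uV R-waves; EMG
#' tone 100/20/5 uV RMS in wake/NREM/REM; saccades of 8 px at 12 per min of
#' REM over a slow 0.5 px ocular drift (30 Hz camera); 20 Hz miniscope with
#' state-tuned cell subclasses. The wake-to-REM transition probability is 0.
#'
#' @param seed Master seed; each generator stage derives its own RNG stream.
#' @param duration_s Recording duration (seconds).
#' @param fs EEG/EMG sampling rate (Hz).
#' @param ... Overrides for any default listed in the function body.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, duration_s = 1800, fs = 1000, ...) {
  cfg <- list(
    seed = seed, duration_s = duration_s, fs = fs, epoch_s = 2.5,
    # semi-Markov hypnogram: exponential-with-floor bout durations (s);
    # light-phase mouse sleep: brief wake bouts, ~1.5 min NREM, ~45 s REM
    mean_dur = c(W = 30, N = 90, R = 45),
    min_dur = c(W = 10, N = 10, R = 10),
    # transition matrix over {W,N,R} given an exit (rows sum to 1; W->R = 0)
    trans = rbind(W = c(W = 0, N = 1.0, R = 0),
                  N = c(W = 0.2, N = 0, R = 0.8),
                  R = c(W = 1.0, N = 0, R = 0)),
    init_state = "W",
    # EEG (uV)
    theta_tonic_hz = 7.5, theta_phasic_hz = 9, theta_amp_uv = 50,
    phasic_amp_factor = 1.5, phasic_rate_per_min = 3, phasic_duration_s = 1.5,
    delta_rms_uv = 60, rem_delta_rms_uv = 15, spindle_rms_uv = 20,
    spindle_rate_per_min = 6, spindle_duration_s = 0.6, wake_rms_uv = 30,
    eeg_noise_uv = 10,
    # EMG / ECG
    emg_rms_uv = c(W = 100, N = 20, R = 5),
    hr_tonic_bpm = 600, hr_phasic_bpm = 660, rwave_uv = -80,
    # pupil (camera clock)
    camera_fs = 30, saccade_rate_per_min = 12, saccade_step_px = 8,
    drift_amp_px = 0.5, drift_freq_hz = 0.2, pupil_radius_px = 12,
    frame_size_px = 120,
    # calcium / miniscope
    miniscope_fs = 20, fov_px = 64, px_size_um = 1.2,
    n_cells = c(RNW = 6, RWN = 6, Wmax = 6, Nmax = 6, unmod = 6),
    # transient rate (Hz) per class (rows) and state (cols W, N, R)
    ca_rates = rbind(RNW = c(W = 0.03, N = 0.15, R = 0.5),
                     RWN = c(W = 0.15, N = 0.03, R = 0.5),
                     Wmax = c(W = 0.4, N = 0.05, R = 0.05),
                     Nmax = c(W = 0.05, N = 0.4, R = 0.05),
                     unmod = c(W = 0.15, N = 0.15, R = 0.15)),
    ca_decay_s = 0.8, ca_amp = 30, ca_footprint_sigma_px = 2,
    neuropil_gain = 0.7, np_amp = 6, ca_noise = 2,
    motion_amp_px = 2, bg_level = 100, off_lens_level = 10,
    # photometry
    photometry_fs = 100, bleach_tau_s = 2000, bleach_frac = 0.2,
    # laser
    laser_duration_s = 120, laser_gap_min = c(13, 17)
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) stop("unknown sim_config fields: ",
                                paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(all(cfg$mean_dur > cfg$min_dur), all(cfg$min_dur > 0),
            cfg$trans["W", "R"] == 0)
  class(cfg) <- "sim_config"
  cfg
}

#' Derive a stage-local RNG seed from the master seed
#'
#' Each generator stage uses its own stream so that, e.g., regenerating the
#' pupil trace does not perturb the EEG. Kept below 2^31.
#'
#' @param seed Master integer seed.
#' @param stage Stage name (character).
#' @return Integer seed.
#' @export
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483629)
}

with_stage_seed <- function(seed, stage, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(stage_seed(seed, stage))
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}

#' Simulate a semi-Markov hypnogram
#'
#' Bout durations are exponential with a per-state floor, implemented as a
#' per-epoch competing-hazard chain (beyond the floor, the exit hazard to each
#' target state is constant), which makes time-varying laser effects on a
#' single transition hazard exact.
#'
#' @param cfg A `sim_config`.
#' @param laser Optional `laser_train`; required if `laser_effect` is given.
#' @param laser_effect Optional named list `list(from=, to=, factor=)`
#'   multiplying the `from -> to` exit hazard during laser intervals.
#' @return List: `hypnogram`, and `episodes` (bout ledger data.frame).
#' @export
simulate_hypnogram <- function(cfg, laser = NULL, laser_effect = NULL) {
  states <- c("W", "N", "R")
  P <- cfg$trans[states, states]
  if (any(rowSums(P) <= 0)) stop("degenerate transition matrix: absorbing state")
  P <- P / rowSums(P)
  dt <- cfg$epoch_s
  n_ep <- floor(cfg$duration_s / dt)
  # per-state hazard rates to each target (1/s) beyond the floor
  haz <- P / (cfg$mean_dur[states] - cfg$min_dur[states])
  floor_ep <- round(cfg$min_dur[states] / dt)
  names(floor_ep) <- states

  laser_on <- if (!is.null(laser)) in_laser(laser, (seq_len(n_ep) - 1) * dt)
              else rep(FALSE, n_ep)

  out <- with_stage_seed(cfg$seed, "hypnogram", {
    u <- runif(n_ep); v <- runif(n_ep)
    s <- character(n_ep)
    cur <- cfg$init_state; tis <- 0L
    for (i in seq_len(n_ep)) {
      s[i] <- cur
      if (tis >= floor_ep[cur]) {
        h <- haz[cur, ]
        if (laser_on[i] && !is.null(laser_effect) && laser_effect$from == cur)
          h[laser_effect$to] <- h[laser_effect$to] * laser_effect$factor
        H <- sum(h)
        if (u[i] < 1 - exp(-H * dt)) {
          cur <- sample_discrete(h / H, v[i])
          tis <- 0L
          next
        }
      }
      tis <- tis + 1L
    }
    s
  })
  h <- hypnogram(out, epoch_s = dt)
  r <- rle(out)
  ends <- cumsum(r$lengths)
  eps <- data.frame(state = r$values,
                    start_s = (ends - r$lengths) * dt,
                    end_s = ends * dt)
  list(hypnogram = h, episodes = eps)
}

sample_discrete <- function(p, u) names(p)[findInterval(u, cumsum(p)) + 1]

# Poisson event onsets within the episodes of one state, clipped to bounds.
# Events are non-overlapping and fully inside their episode.
poisson_events_in_state <- function(eps, rate_per_min, duration_s) {
  onsets <- numeric(0)
  for (i in seq_len(nrow(eps))) {
    t0 <- eps$start_s[i]; t1 <- eps$end_s[i]
    t <- t0
    repeat {
      t <- t + rexp(1, rate_per_min / 60)
      if (t + duration_s > t1) break
      onsets <- c(onsets, t)
      t <- t + duration_s          # no overlap
    }
  }
  if (length(onsets) == 0)
    return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  data.frame(start_s = onsets, end_s = onsets + duration_s)
}

#' Simulate EEG and EMG traces for a hypnogram
#'
#' EEG = state-gated sum of a 1.5-4 Hz delta process and spindle bursts
#' (NREM), a frequency-modulated theta oscillation (REM; frequency steps from
#' the tonic to the phasic value and amplitude rises x1.5 inside injected
#' phasic events), and low-passed broadband noise (wake), plus white sensor
#' noise. EMG = white noise at the state RMS plus a biphasic ECG template at
#' the configured instantaneous rate, elevated during phasic events.
#'
#' @param cfg A `sim_config`.
#' @param truth List containing at least `hypnogram` (from
#'   [simulate_hypnogram()]); phasic events and R-wave times are added.
#' @return List: `recording` (a `signal_recording` with `EEG_frontal`,
#'   `EEG_parietal`, `EMG`), and the updated `truth` ledger with
#'   `phasic_events` (data.frame start_s/end_s) and `rwave_times_s`.
#' @export
simulate_eeg_emg <- function(cfg, truth) {
  if (cfg$fs < 4 * cfg$theta_phasic_hz)
    stop("fs too low for the theta band")
  h <- truth$hypnogram
  fs <- cfg$fs
  n <- round(length(h$states) * h$epoch_s * fs)
  tt <- (seq_len(n) - 1) / fs
  st <- h$states[pmin(floor(tt / h$epoch_s) + 1, length(h$states))]

  rem_eps <- episodes(h, "R", bridge_microarousal_s = 0)
  phasic <- with_stage_seed(cfg$seed, "phasic", {
    if (cfg$phasic_rate_per_min > 0 && nrow(rem_eps) > 0)
      poisson_events_in_state(rem_eps, cfg$phasic_rate_per_min,
                              cfg$phasic_duration_s)
    else data.frame(start_s = numeric(0), end_s = numeric(0))
  })
  in_phasic <- rep(FALSE, n)
  for (i in seq_len(nrow(phasic))) {
    in_phasic[tt >= phasic$start_s[i] & tt < phasic$end_s[i]] <- TRUE
  }

  eeg <- with_stage_seed(cfg$seed, "eeg", {
    # REM theta: phase-continuous frequency modulation
    f_inst <- ifelse(in_phasic, cfg$theta_phasic_hz, cfg$theta_tonic_hz)
    theta <- sin(2 * pi * cumsum(f_inst) / fs) * cfg$theta_amp_uv *
      ifelse(in_phasic, cfg$phasic_amp_factor, 1)
    delta <- bandpass_filter(rnorm(n), fs, 1.5, 4)
    delta <- delta / sd(delta) * cfg$delta_rms_uv
    sigma <- bandpass_filter(rnorm(n), fs, 10, 15)
    sigma <- sigma / sd(sigma) * cfg$spindle_rms_uv
    sp_env <- rep(0, n)
    n_eps <- episodes(h, "N", bridge_microarousal_s = 0)
    if (nrow(n_eps) > 0 && cfg$spindle_rate_per_min > 0) {
      sp <- poisson_events_in_state(n_eps, cfg$spindle_rate_per_min,
                                    cfg$spindle_duration_s)
      for (i in seq_len(nrow(sp)))
        sp_env[tt >= sp$start_s[i] & tt < sp$end_s[i]] <- 1
    }
    broad <- lowpass_filter(rnorm(n), fs, 50)
    broad <- broad / sd(broad) * cfg$wake_rms_uv
    noise1 <- rnorm(n, sd = cfg$eeg_noise_uv)
    noise2 <- rnorm(n, sd = cfg$eeg_noise_uv)
    # REM keeps residual slow activity so the theta/delta ratio stays bounded
    rem_delta <- delta * (cfg$rem_delta_rms_uv / cfg$delta_rms_uv)
    par <- (st == "R") * (theta + rem_delta) +
      (st == "N") * (delta + sp_env * sigma) +
      (st == "W") * broad + noise1
    fro <- (st == "R") * (0.5 * theta + rem_delta) +
      (st == "N") * (1.2 * delta + sp_env * sigma) +
      (st == "W") * broad + noise2
    list(parietal = par, frontal = fro)
  })

  ecg <- with_stage_seed(cfg$seed, "ecg", {
    rwaves <- numeric(0)
    if (cfg$rwave_uv != 0) {
      t <- 0
      while (t < cfg$duration_s) {
        bpm <- if (any(in_phasic) &&
                   in_phasic[min(n, floor(t * fs) + 1)]) cfg$hr_phasic_bpm
               else cfg$hr_tonic_bpm
        t <- t + 60 / bpm
        if (t < cfg$duration_s) rwaves <- c(rwaves, t)
      }
    }
    rwaves
  })
  emg <- with_stage_seed(cfg$seed, "emg", {
    rms <- cfg$emg_rms_uv[st]
    e <- rnorm(n) * rms
    if (length(ecg) > 0) {
      # biphasic template: sharp negative R deflection + small late positive lobe
      tpl_t <- seq(-0.015, 0.02, by = 1 / fs)
      tpl <- cfg$rwave_uv * exp(-(tpl_t / 0.004)^2) -
        0.3 * cfg$rwave_uv * exp(-((tpl_t - 0.009) / 0.005)^2)
      for (rt in ecg) {
        i0 <- round(rt * fs) + 1 + round(tpl_t[1] * fs)
        idx <- i0:(i0 + length(tpl) - 1)
        ok <- idx >= 1 & idx <= n
        e[idx[ok]] <- e[idx[ok]] + tpl[ok]
      }
    }
    e
  })

  truth$phasic_events <- phasic
  truth$rwave_times_s <- ecg
  list(recording = signal_recording(
         list(EEG_frontal = eeg$frontal, EEG_parietal = eeg$parietal, EMG = emg),
         fs = fs),
       truth = truth)
}

#' Simulate a pupil-position trace (and optionally rendered frames)
#'
#' Gaze is piecewise constant with step displacements at ledgered saccade
#' times (Poisson within REM), superimposed on a slow, smooth, near-circular
#' ocular drift whose acceleration stays well below the saccade-detection
#' criterion.
#'
#' @param cfg A `sim_config`.
#' @param truth Ledger list containing `hypnogram`; saccade times are added.
#' @param render If TRUE also renders grayscale frames (bright field, dark
#'   pupil disk) as an array `frame_size_px x frame_size_px x n_frames`.
#' @return List: `trace` (data.frame t_s/x_px/y_px/valid), `frames` (or NULL),
#'   updated `truth` with `saccade_times_s`.
#' @export
simulate_pupil <- function(cfg, truth, render = FALSE) {
  h <- truth$hypnogram
  fs <- cfg$camera_fs
  n <- round(cfg$duration_s * fs)
  tt <- (seq_len(n) - 1) / fs
  rem_eps <- episodes(h, "R", bridge_microarousal_s = 0)
  res <- with_stage_seed(cfg$seed, "pupil", {
    sac <- if (cfg$saccade_rate_per_min > 0 && nrow(rem_eps) > 0)
      poisson_events_in_state(rem_eps, cfg$saccade_rate_per_min, 1 / fs)$start_s
    else numeric(0)
    cx <- cfg$frame_size_px / 2
    x <- rep(cx, n); y <- rep(cx, n)
    for (ts in sac) {
      i0 <- floor(ts * fs) + 1
      # bias the direction back toward center once the gaze wanders off,
      # so positions stay inside the frame without discontinuities
      d <- sqrt((x[i0] - cx)^2 + (y[i0] - cx)^2)
      ang <- if (d > 15) atan2(cx - y[i0], cx - x[i0]) + runif(1, -pi / 3, pi / 3)
             else runif(1, 0, 2 * pi)
      x[i0:n] <- x[i0:n] + cfg$saccade_step_px * cos(ang)
      y[i0:n] <- y[i0:n] + cfg$saccade_step_px * sin(ang)
    }
    if (cfg$drift_amp_px > 0) {
      ph <- runif(1, 0, 2 * pi)
      dl <- runif(1, -pi / 12, pi / 12)   # near-circular: smooth speed
      x <- x + cfg$drift_amp_px * sin(2 * pi * cfg$drift_freq_hz * tt + ph)
      y <- y + cfg$drift_amp_px * cos(2 * pi * cfg$drift_freq_hz * tt + ph + dl)
    }
    list(x = x, y = y, sac = sac)
  })
  trace <- data.frame(t_s = tt, x_px = res$x, y_px = res$y, valid = TRUE)
  frames <- NULL
  if (render) {
    frames <- array(0, dim = c(cfg$frame_size_px, cfg$frame_size_px, n))
    for (i in seq_len(n))
      frames[, , i] <- render_pupil_frame(res$x[i], res$y[i],
                                          cfg$frame_size_px, cfg$pupil_radius_px)
  }
  truth$saccade_times_s <- res$sac
  list(trace = trace, frames = frames, truth = truth)
}

#' Simulate independent laser-aligned transition trials
#'
#' Generates `m` trials for the transition-probability analyses, each from an
#' independent realization of the semi-Markov chain (burn-in, then a 120 s
#' baseline window followed by the laser interval), emulating trials pooled
#' across sessions and animals. An optional laser effect multiplies one
#' transition hazard during the laser interval.
#'
#' @param cfg A `sim_config`.
#' @param m Number of trials.
#' @param laser_effect Optional `list(from=, to=, factor=)` as in
#'   [simulate_hypnogram()].
#' @param burn_in_s Chain burn-in before the baseline window (s).
#' @param horizon_s,epoch_s Passed to [transition_trials()].
#' @return A `transition_trials` object with `m` rows.
#' @export
simulate_transition_trials <- function(cfg, m, laser_effect = NULL,
                                       burn_in_s = 400, horizon_s = 120,
                                       epoch_s = 10) {
  onset <- burn_in_s + horizon_s
  dur <- onset + horizon_s + epoch_s + 2 * cfg$epoch_s
  las <- laser_train(onset, horizon_s)
  lasm <- list(); basm <- list()
  init_states <- with_stage_seed(cfg$seed, "trial_inits",
                                 sample(c("W", "N", "R"), m, replace = TRUE))
  for (i in seq_len(m)) {
    ci <- cfg
    ci$duration_s <- dur
    ci$seed <- stage_seed(cfg$seed, paste0("trial", i))
    ci$init_state <- init_states[i]
    hy <- simulate_hypnogram(ci, laser = las, laser_effect = laser_effect)
    tr <- transition_trials(hy$hypnogram, las, horizon_s, epoch_s)
    lasm[[i]] <- tr$laser; basm[[i]] <- tr$baseline
  }
  structure(list(laser = do.call(rbind, lasm), baseline = do.call(rbind, basm),
                 epoch_s = epoch_s, horizon_s = horizon_s,
                 d = seq(0, horizon_s, by = epoch_s)),
            class = "transition_trials")
}

#' Render one synthetic pupil frame
#'
#' Bright field (0.8) with a dark disk (0.1) of given radius at (x, y); the
#' disk edge is linearly anti-aliased over one pixel so the rendered centroid
#' tracks the commanded sub-pixel position.
#'
#' @param x,y Pupil center (px, 1-based pixel coordinates).
#' @param size Frame side length (px).
#' @param radius Pupil radius (px).
#' @return Numeric matrix `size x size` in [0, 1].
#' @export
render_pupil_frame <- function(x, y, size = 120, radius = 12) {
  gx <- matrix(seq_len(size), size, size)
  gy <- matrix(seq_len(size), size, size, byrow = TRUE)
  r <- sqrt((gx - x)^2 + (gy - y)^2)
  edge <- pmin(pmax(r - radius, -0.5), 0.5) + 0.5   # 0 inside, 1 outside
  0.1 + 0.7 * edge
}
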