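# Calcium-imaging generators: a miniscope movie with state-tuned cells,
# neuropil background, blood-vessel / off-lens calibration regions and
# ledgered motion, plus a two-channel fiber-photometry pair and a trace-level
# generator for the statistical analyses.

ca_kernel_trace <- function(spikes, decay_frames) {
  stats::filter(spikes, exp(-1 / decay_frames), method = "recursive")
}

state_per_frame <- function(h, fs, n) {
  tt <- (seq_len(n) - 1) / fs
  h$states[pmin(floor(tt / h$epoch_s) + 1, length(h$states))]
}

#' Simulate per-cell calcium activity traces
#'
#' Trace-level generator (no movie): per cell, Poisson transient onsets at the
#' state-dependent rate of its subclass, convolved with an exponential decay
#' kernel, plus white noise. Used for the statistics on brain-state subclasses
#' where pixel-level detail is irrelevant.
#'
#' @param cfg A `sim_config`.
#' @param truth Ledger list with `hypnogram`.
#' @param phasic_coupling Optional `list(class=, factor=)`: multiplies the
#'   transient rate of one subclass inside ledgered phasic events (requires
#'   `truth$phasic_events`).
#' @param prerem_ramp_s If > 0, REM-max cells ramp linearly from their NREM to
#'   their REM rate over this many seconds before each REM onset.
#' @param noise_sd Additive white-noise SD on the dF/F-like trace.
#' @return List: `dff` (cells x frames), `labels` (subclass per cell), `fs`,
#'   `clean` (noiseless traces), updated `truth`.
#' @export
simulate_roi_traces <- function(cfg, truth, phasic_coupling = NULL,
                                prerem_ramp_s = 0, noise_sd = 0.05) {
  h <- truth$hypnogram
  fs <- cfg$miniscope_fs
  n <- round(cfg$duration_s * fs)
  st <- state_per_frame(h, fs, n)
  labels <- rep(names(cfg$n_cells), cfg$n_cells)
  K <- length(labels)
  decay_f <- cfg$ca_decay_s * fs
  tt <- (seq_len(n) - 1) / fs

  in_phasic <- rep(FALSE, n)
  if (!is.null(phasic_coupling) && !is.null(truth$phasic_events)) {
    pe <- truth$phasic_events
    for (i in seq_len(nrow(pe)))
      in_phasic[tt >= pe$start_s[i] & tt < pe$end_s[i]] <- TRUE
  }
  ramp <- rep(0, n)
  if (prerem_ramp_s > 0) {
    rem_eps <- episodes(h, "R", bridge_microarousal_s = 0)
    for (on in rem_eps$start_s) {
      sel <- tt >= on - prerem_ramp_s & tt < on
      ramp[sel] <- (tt[sel] - (on - prerem_ramp_s)) / prerem_ramp_s
    }
  }

  res <- with_stage_seed(cfg$seed, "roi_traces", {
    clean <- matrix(0, K, n)
    spikes <- vector("list", K)
    for (k in seq_len(K)) {
      rates <- cfg$ca_rates[labels[k], st]
      if (prerem_ramp_s > 0 && labels[k] %in% c("RNW", "RWN")) {
        r_target <- cfg$ca_rates[labels[k], "R"]
        rates <- rates + ramp * (r_target - rates) * (st == "N")
      }
      if (!is.null(phasic_coupling) && labels[k] == phasic_coupling$class)
        rates <- rates * ifelse(in_phasic, phasic_coupling$factor, 1)
      spk <- as.numeric(runif(n) < rates / fs)
      spikes[[k]] <- tt[spk > 0]
      clean[k, ] <- as.numeric(ca_kernel_trace(spk, decay_f))
    }
    list(clean = clean,
         dff = clean + matrix(rnorm(K * n, sd = noise_sd), K, n),
         spikes = spikes)
  })
  truth$cell_labels <- labels
  truth$spike_times <- res$spikes
  list(dff = res$dff, clean = res$clean, labels = labels, fs = fs, truth = truth)
}

#' Simulate a miniscope calcium movie with ground truth
#'
#' Renders Gaussian-footprint cells (subclass-tuned transient rates), a shared
#' zero-mean neuropil fluctuation entering ROI pixels scaled by the configured
#' gain and non-ROI tissue at full strength, a dark blood-vessel stripe and an
#' off-lens margin (built so the mean-intensity calibration ratio equals the
#' neuropil gain), white noise, and ledgered integer motion shifts (applied
#' circularly).
#'
#' @param cfg A `sim_config`.
#' @param truth Ledger list with `hypnogram`.
#' @return List: `movie` (array fov x fov x frames), `rois` (a [roi_set()]
#'   built from the true footprints incl. calibration regions), updated
#'   `truth` with `cell_labels`, `cell_traces` (clean transients), `shifts`
#'   (data.frame dx/dy per frame), `np_trace`, `footprints`.
#' @export
simulate_calcium <- function(cfg, truth) {
  h <- truth$hypnogram
  fs <- cfg$miniscope_fs
  n <- round(cfg$duration_s * fs)
  st <- state_per_frame(h, fs, n)
  fov <- cfg$fov_px
  labels <- rep(names(cfg$n_cells), cfg$n_cells)
  K <- length(labels)

  gx <- matrix(seq_len(fov), fov, fov)
  gy <- matrix(seq_len(fov), fov, fov, byrow = TRUE)
  cx <- (fov + 1) / 2
  rr <- sqrt((gx - cx)^2 + (gy - cx)^2)
  lens_r <- fov / 2 - 2
  in_lens <- rr <= lens_r
  vessel <- abs(gx - gy) <= 1 & in_lens

  out <- with_stage_seed(cfg$seed, "calcium", {
    # cell centers: in-lens, off the vessel and margin, minimally separated
    centers <- matrix(NA_real_, K, 2)
    k <- 1; tries <- 0
    while (k <= K) {
      tries <- tries + 1
      if (tries > 50000) stop("cells exceed the field of view: cannot place ",
                              K, " cells in a ", fov, " px lens")
      p <- runif(2, 7, fov - 6)
      if (sqrt(sum((p - cx)^2)) > lens_r - 5) next
      if (abs(p[1] - p[2]) < 7.5) next   # clear of the vessel stripe
      if (k > 1 && min(sqrt(rowSums(sweep(centers[seq_len(k - 1), , drop = FALSE],
                                          2, p)^2))) < 6) next
      centers[k, ] <- p; k <- k + 1
    }
    fp <- vapply(seq_len(K), function(k) {
      f <- exp(-((gx - centers[k, 1])^2 + (gy - centers[k, 2])^2) /
                 (2 * cfg$ca_footprint_sigma_px^2))
      f[!in_lens] <- 0
      as.numeric(f)
    }, numeric(fov * fov))
    roi_mask <- matrix(apply(fp, 1, max) > 0.25, fov, fov)

    # transients
    decay_f <- cfg$ca_decay_s * fs
    traces <- matrix(0, K, n)
    for (k in seq_len(K)) {
      spk <- as.numeric(runif(n) < cfg$ca_rates[labels[k], st] / fs)
      traces[k, ] <- as.numeric(ca_kernel_trace(spk, decay_f))
    }
    np <- if (cfg$np_amp > 0) {
      z <- lowpass_filter(rnorm(n), fs, 0.5)
      z / sd(z) * cfg$np_amp
    } else rep(0, n)

    # static base image and neuropil weight map
    base <- matrix(cfg$off_lens_level, fov, fov)
    base[in_lens] <- cfg$bg_level
    base[vessel] <- cfg$off_lens_level +
      cfg$neuropil_gain * (cfg$bg_level - cfg$off_lens_level)
    w_np <- matrix(0, fov, fov)
    w_np[in_lens] <- 1
    w_np[roi_mask] <- cfg$neuropil_gain
    w_np[vessel] <- cfg$neuropil_gain

    # bounded random-walk jitter (integer px)
    walk <- function() {
      d <- integer(n); cur <- 0L
      steps <- sample(c(-1L, 0L, 1L), n, replace = TRUE)
      steps[1] <- 0L   # shifts are defined relative to the session start
      for (i in seq_len(n)) {
        cur <- max(-cfg$motion_amp_px, min(cfg$motion_amp_px, cur + steps[i]))
        d[i] <- cur
      }
      d
    }
    shifts <- if (cfg$motion_amp_px > 0) data.frame(dx = walk(), dy = walk())
              else data.frame(dx = integer(n), dy = integer(n))

    flat <- as.numeric(base) + fp %*% (cfg$ca_amp * traces)
    flat <- flat + as.numeric(w_np) %o% np
    flat <- flat + matrix(rnorm(fov * fov * n, sd = cfg$ca_noise), fov * fov, n)
    movie <- array(flat, dim = c(fov, fov, n))
    if (cfg$motion_amp_px > 0) {
      for (i in seq_len(n))
        movie[, , i] <- roll_matrix(movie[, , i], shifts$dx[i], shifts$dy[i])
    }
    list(movie = movie, centers = centers, fp = fp, traces = traces, np = np,
         shifts = shifts, roi_mask = roi_mask)
  })

  masks <- lapply(seq_len(K), function(k)
    matrix(out$fp[, k] > 0.25, fov, fov))
  # calibration regions: a vessel patch, a nearby ROI-free tissue patch,
  # and an off-lens corner patch
  near <- in_lens & !vessel & !out$roi_mask &
    (abs(gx - gy) > 3) & (abs(gx - gy) <= 8)
  rois <- roi_set(masks,
                  vessel = vessel,
                  near_vessel = near,
                  off_lens = !in_lens)

  truth$cell_labels <- labels
  truth$cell_centers <- out$centers
  truth$cell_traces <- out$traces
  truth$np_trace <- out$np
  truth$shifts <- out$shifts
  truth$footprints <- out$fp
  list(movie = out$movie, rois = rois, fs = fs, truth = truth)
}

#' Circularly shift a matrix by integer offsets
#' @param m Matrix.
#' @param dx,dy Integer shifts along rows / columns.
#' @return Shifted matrix.
#' @export
roll_matrix <- function(m, dx, dy) {
  nr <- nrow(m); nc <- ncol(m)
  m[((seq_len(nr) - 1 - dx) %% nr) + 1, ((seq_len(nc) - 1 - dy) %% nc) + 1]
}

#' Write / read a movie as a multi-page TIFF (float32)
#' @param movie Array `h x w x frames` (arbitrary fluorescence units).
#' @param path TIFF path.
#' @param scale Intensity divisor applied before writing (values must land in
#'   [0, 1] for TIFF storage); the reader multiplies it back.
#' @export
write_movie_tiff <- function(movie, path, scale = max(movie) * 1.05) {
  frames <- lapply(seq_len(dim(movie)[3]), function(i)
    pmax(movie[, , i], 0) / scale)
  tiff::writeTIFF(frames, path, bits.per.sample = 32L, reduce = FALSE)
  writeLines(sprintf("%.10g", scale), paste0(path, ".scale"))
  invisible(path)
}

#' @rdname write_movie_tiff
#' @export
read_movie_tiff <- function(path) {
  frames <- tiff::readTIFF(path, all = TRUE)
  scale_file <- paste0(path, ".scale")
  sc <- if (file.exists(scale_file)) as.numeric(readLines(scale_file)[1]) else 1
  arr <- array(0, dim = c(nrow(frames[[1]]), ncol(frames[[1]]), length(frames)))
  for (i in seq_along(frames)) arr[, , i] <- frames[[i]] * sc
  arr
}

#' Simulate a two-channel fiber-photometry recording
#'
#' 465 nm = bleaching trend + population calcium transient + shared artifact;
#' 405 nm (isosbestic) = bleaching trend + shared artifact only. Bleaching is
#' exponential with ledgered coefficients.
#'
#' @param cfg A `sim_config`.
#' @param truth Ledger with `hypnogram`.
#' @param n_pop Number of pooled population cells driving the 465 transient.
#' @return List: `photometry` (data.frame t_s/f465/f405), updated `truth` with
#'   `pop_trace` and `bleach` coefficients.
#' @export
simulate_photometry <- function(cfg, truth, n_pop = 40) {
  h <- truth$hypnogram
  fs <- cfg$photometry_fs
  n <- round(cfg$duration_s * fs)
  st <- state_per_frame(h, fs, n)
  out <- with_stage_seed(cfg$seed, "photometry", {
    rate <- cfg$ca_rates["RNW", st] * n_pop
    spk <- rpois(n, rate / fs)
    pop <- as.numeric(ca_kernel_trace(spk, cfg$ca_decay_s * fs))
    pop <- pop / max(mean(pop), 1e-12)          # unit-mean population signal
    tt <- (seq_len(n) - 1) / fs
    bleach <- 1 - cfg$bleach_frac * (1 - exp(-tt / cfg$bleach_tau_s))
    art <- lowpass_filter(rnorm(n), fs, 1)
    art <- art / sd(art) * 0.01
    f465 <- 2.0 * bleach * (1 + 0.06 * pop) + art + rnorm(n, sd = 0.004)
    f405 <- 1.0 * bleach + art + rnorm(n, sd = 0.004)
    list(pop = pop, f465 = f465, f405 = f405)
  })
  truth$pop_trace <- out$pop
  truth$bleach <- c(frac = cfg$bleach_frac, tau_s = cfg$bleach_tau_s)
  list(photometry = data.frame(t_s = (seq_len(n) - 1) / fs,
                               f465 = out$f465, f405 = out$f405),
       fs = fs, truth = truth)
}

#' One-call synthetic recording
#'
#' Chains [simulate_hypnogram()], [simulate_eeg_emg()] and (optionally)
#' [simulate_pupil()] into a complete synthetic session with ground truth.
#'
#' @param cfg A `sim_config`.
#' @param laser,laser_effect Passed to [simulate_hypnogram()].
#' @param pupil If TRUE also simulate the pupil trace.
#' @return List: `recording`, `hypnogram`, `truth`, optionally `pupil`.
#' @export
simulate_recording <- function(cfg, laser = NULL, laser_effect = NULL,
                               pupil = FALSE) {
  hy <- simulate_hypnogram(cfg, laser = laser, laser_effect = laser_effect)
  truth <- list(hypnogram = hy$hypnogram, bouts = hy$episodes)
  ee <- simulate_eeg_emg(cfg, truth)
  out <- list(recording = ee$recording, hypnogram = hy$hypnogram,
              truth = ee$truth)
  if (pupil) {
    pu <- simulate_pupil(cfg, out$truth)
    out$pupil <- pu$trace
    out$truth <- pu$truth
  }
  out
}
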