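small_ca <- function(seed = 11, duration_s = 150, ...) {
  cfg <- sim_config(seed = seed, duration_s = duration_s,
                    n_cells = c(RNW = 3, RWN = 3, Wmax = 3, Nmax = 3, unmod = 3),
                    ...)
  hy <- simulate_hypnogram(cfg)
  ca <- simulate_calcium(cfg, list(hypnogram = hy$hypnogram))
  list(cfg = cfg, h = hy$hypnogram, ca = ca)
}

test_that("activity map: constant movies are flat, flicker is localized", {
  mv <- array(7, dim = c(12, 12, 20))
  expect_true(all(activity_map(mv) == 0))
  expect_true(all(activity_map(mv[, , 1, drop = FALSE]) == 0))
  set.seed(1)
  mv[5, 8, ] <- 7 + rnorm(20, sd = 3)
  m <- activity_map(mv)
  pk <- which(m == max(m), arr.ind = TRUE)[1, ]   # ties within the 2x2 box
  expect_lte(abs(pk[["row"]] - 5), 1)
  expect_lte(abs(pk[["col"]] - 8), 1)
})

test_that("activity map equals the literal three-loop reference", {
  for (s in 1:5) {
    set.seed(s)
    mv <- array(runif(16 * 16 * 50, 50, 150), dim = c(16, 16, 50))
    expect_equal(activity_map(mv), oracle_activity_map(mv), tolerance = 1e-12)
  }
})

test_that("motion correction recovers ledgered shifts exactly and is idempotent", {
  s <- small_ca(seed = 13, duration_s = 60)
  mc <- motion_correct(s$ca$movie)
  expect_equal(mc$shifts$dx, s$ca$truth$shifts$dx)
  expect_equal(mc$shifts$dy, s$ca$truth$shifts$dy)
  mc2 <- motion_correct(mc$movie)
  expect_true(all(mc2$shifts$dx == 0 & mc2$shifts$dy == 0))
  # a zero-motion movie yields all-zero shifts
  s0 <- small_ca(seed = 14, duration_s = 40, motion_amp_px = 0)
  mc0 <- motion_correct(s0$ca$movie)
  expect_true(all(mc0$shifts$dx == 0 & mc0$shifts$dy == 0))
})

test_that("dF/F extraction recovers the neuropil factor and the transients", {
  s <- small_ca(seed = 15, duration_s = 150)
  mc <- motion_correct(s$ca$movie)
  tx <- extract_dff(mc$movie, s$ca$rois, fs = s$cfg$miniscope_fs)
  expect_lt(abs(tx$c - s$cfg$neuropil_gain) / s$cfg$neuropil_gain, 0.1)
  cors <- vapply(seq_len(nrow(tx$dff)), function(k)
    cor(tx$dff[k, ], s$ca$truth$cell_traces[k, ]), numeric(1))
  expect_gte(min(cors), 0.9)
  # stored traces satisfy the subtraction identity exactly
  expect_equal(tx$F_subt, tx$F - tx$c * tx$F_np, tolerance = 1e-12)
  # baseline is affine in time
  for (k in c(1, nrow(tx$B))) {
    d2 <- diff(tx$B[k, ], differences = 2)
    expect_lt(max(abs(d2)), 1e-8)
  }
})

test_that("a pure linear bleach with no transients gives near-zero dF/F", {
  fov <- 32; n <- 800
  tt <- seq_len(n)
  base <- matrix(100, fov, fov)
  mv <- array(0, dim = c(fov, fov, n))
  for (i in seq_len(n)) mv[, , i] <- base * (1 - 2e-4 * i)
  gx <- matrix(seq_len(fov), fov, fov); gy <- t(gx)
  mask <- (gx - 10)^2 + (gy - 10)^2 <= 9
  rois <- roi_set(list(mask), vessel = NULL, near_vessel = NULL, off_lens = NULL)
  tx <- extract_dff(mv, rois, fs = 20, c_override = 0.7)
  expect_lt(max(abs(tx$dff)), 0.01)
})

test_that("photometry dF/F is exact for a proportional pair and removes bleach", {
  set.seed(3)
  n <- 60 * 100
  f405 <- 1 + 0.2 * sin(seq_len(n) / 2000) + rnorm(n, sd = 0.001)
  out <- photometry_dff(2 * f405, f405, fs = 100)
  expect_lt(max(abs(out$dff)), 1e-3)
  expect_error(photometry_dff(rnorm(n), rep(1, n), fs = 100), "degenerate")

  cfg <- sim_config(seed = 23, duration_s = 600)
  hy <- simulate_hypnogram(cfg)
  ph <- simulate_photometry(cfg, list(hypnogram = hy$hypnogram))
  res <- photometry_dff(ph$photometry$f465, ph$photometry$f405, cfg$photometry_fs)
  expect_gte(cor(res$dff, ph$truth$pop_trace), 0.9)
  tr <- coef(lm(res$dff ~ ph$photometry$t_s))[2] * 60   # dF/F per minute
  expect_lt(abs(tr), 0.01)
  # a shared artifact leaves dF/F essentially unchanged
  art <- lowpass_filter(rnorm(n = nrow(ph$photometry)), cfg$photometry_fs, 1) * 0.01
  res2 <- photometry_dff(ph$photometry$f465 + art, ph$photometry$f405 + art,
                         cfg$photometry_fs)
  expect_gt(cor(res2$dff, res$dff), 0.98)
})

test_that("ROI matching recovers a rigid translation and honours the 50% gate", {
  s <- small_ca(seed = 17, duration_s = 40)
  rois_a <- s$ca$rois
  shift_all <- function(rois, dx, dy) {
    masks <- lapply(rois$masks, sleepkit:::shift_mask, dx = dx, dy = dy)
    roi_set(masks, vessel = NULL, near_vessel = NULL, off_lens = NULL)
  }
  rois_b <- shift_all(rois_a, 3, -2)
  m <- match_rois(rois_a, rois_b, rot_deg = 0)
  expect_equal(m$transform$dx, 3)
  expect_equal(m$transform$dy, -2)
  expect_equal(nrow(m$pairs), length(rois_a$masks))
  expect_equal(m$pairs$a, m$pairs$b)

  # disjoint sets pair nothing
  empty <- matrix(FALSE, 64, 64)
  far_a <- empty; far_a[5:8, 5:8] <- TRUE
  far_b <- empty; far_b[50:53, 50:53] <- TRUE
  m0 <- match_rois(roi_set(list(far_a)), roi_set(list(far_b)),
                   rot_deg = 0, max_shift_px = 3)
  expect_equal(nrow(m0$pairs), 0)

  # overlap just under 50% of the smaller ROI is not matched
  # overlap below 50% of the smaller ROI even after the +-1 px refinement
  a <- empty; a[10:19, 10:19] <- TRUE          # 100 px
  b <- empty; b[10:19, 17:26] <- TRUE          # overlap 30 px (40 after +-1)
  m1 <- match_rois(roi_set(list(a)), roi_set(list(b)), rot_deg = 0,
                   max_shift_px = 0)
  expect_equal(nrow(m1$pairs), 0)
  b2 <- empty; b2[10:19, 13:22] <- TRUE        # overlap 70 px
  m2 <- match_rois(roi_set(list(a)), roi_set(list(b2)), rot_deg = 0,
                   max_shift_px = 0)
  expect_equal(nrow(m2$pairs), 1)
})

test_that("subclass classification gates on ANOVA and orders means via Tukey", {
  cfg <- sim_config(seed = 19, duration_s = 900)
  hy <- simulate_hypnogram(cfg)
  tr <- simulate_roi_traces(cfg, list(hypnogram = hy$hypnogram))
  cl <- classify_subclasses(tr$dff, hy$hypnogram, cfg$miniscope_fs)
  acc <- mean(cl$table$label == tr$labels)
  expect_gte(acc, 0.9)
  expect_equal(sum(cl$proportions), 1)
  # a missing state is an error naming it
  h2 <- hy$hypnogram; h2$states[h2$states == "R"] <- "N"
  expect_error(classify_subclasses(tr$dff, h2, cfg$miniscope_fs), "R")
  # noiseless construction: REM > NREM > wake means map to RNW
  n <- 3 * 400
  st <- rep(c("W", "N", "R"), each = 400)
  h3 <- hypnogram(st, epoch_s = 2.5)
  base <- rep(c(0, 0.5, 1.0), each = 400 * 50)
  dff3 <- matrix(rep(base, 2), 2, byrow = TRUE) +
    matrix(rnorm(2 * length(base), sd = 0.01), 2)
  cl3 <- classify_subclasses(dff3, h3, fs = 20)
  expect_true(all(cl3$table$label == "RNW"))
})

test_that("transition alignment enforces the preceding-episode rules", {
  # NREM of 50 s before REM: excluded; 70 s: included
  st <- c(rep("W", 30), rep("N", 20), rep("R", 20),   # 50 s NREM -> excluded
          rep("W", 30), rep("N", 28), rep("R", 20), rep("W", 10))
  h <- hypnogram(st, epoch_s = 2.5)
  tr <- sleepkit:::qualifying_transitions(h, "N", "R")
  expect_equal(length(tr), 1)
  expect_equal(tr, (30 + 20 + 20 + 30 + 28) * 2.5)
  # microarousals bridge the NREM episode for the inclusion rule
  st2 <- c(rep("W", 5), rep("N", 12), "W", rep("N", 12), rep("R", 10))
  h2 <- hypnogram(st2, epoch_s = 2.5)
  expect_equal(length(sleepkit:::qualifying_transitions(h2, "N", "R")), 1)
  # REM -> Wake requires only 10 s of REM
  expect_equal(length(sleepkit:::qualifying_transitions(h2, "R", "W")), 0)
  st3 <- c(st2, rep("W", 10))
  expect_equal(length(sleepkit:::qualifying_transitions(hypnogram(st3, 2.5),
                                                        "R", "W")), 1)
})

test_that("ramping cells show pre-onset modulation; null cells stay flat", {
  cfg <- sim_config(seed = 29, duration_s = 1800,
                    n_cells = c(RNW = 8, RWN = 0, Wmax = 0, Nmax = 0, unmod = 8))
  hy <- simulate_hypnogram(cfg)
  tr <- simulate_roi_traces(cfg, list(hypnogram = hy$hypnogram),
                            prerem_ramp_s = 20)
  al <- align_to_transitions(tr$dff, hy$hypnogram, cfg$miniscope_fs,
                             tr$labels, "N", "R")
  skip_if(is.null(al$subclasses$RNW), "no qualifying transitions for this seed")
  rnw <- al$subclasses$RNW
  expect_lt(rnw$p_rm_anova, 0.05)
  expect_true(any(rnw$sig_bins))
  # the REM-side bins rise above the baseline bin
  expect_gt(mean(rnw$mean[7:9]), rnw$mean[1])
})

test_that("phasic-event contrasts use equal-duration baselines and find coupling", {
  cfg <- sim_config(seed = 31, duration_s = 1500,
                    n_cells = c(RNW = 0, RWN = 10, Wmax = 0, Nmax = 0, unmod = 10))
  hy <- simulate_hypnogram(cfg)
  rem <- episodes(hy$hypnogram, "R", bridge_microarousal_s = 0)
  ev <- sleepkit:::poisson_events_in_state(rem, 3, 1.5)
  ev$episode_id <- vapply(ev$start_s, function(t0)
    rem$episode_id[rem$start_s <= t0 & rem$end_s > t0][1], numeric(1))
  truth <- list(hypnogram = hy$hypnogram, phasic_events = ev)
  tr <- simulate_roi_traces(cfg, truth,
                            phasic_coupling = list(class = "RWN", factor = 8))
  res <- phasic_event_activity(tr$dff, cfg$miniscope_fs, ev, rem, tr$labels)
  skip_if(length(res) == 0, "no usable events for this seed")
  expect_lt(res$RWN$p, 0.05)
  expect_gt(res$RWN$mean_event, res$RWN$mean_baseline)
  expect_gt(res$unmod$p, 0.05)
})

test_that("cross-correlation peaks at the injected lag with the documented sign", {
  cfg <- sim_config(seed = 37, duration_s = 600, mean_dur = c(W = 30, N = 500, R = 45),
                    init_state = "N")
  sim <- simulate_recording(cfg)
  sg <- spectrogram(get_channel(sim$recording, "EEG_parietal"), cfg$fs,
                    window_s = 2.5, step_s = 0.5, psd_window_s = 2)
  npw <- sg$power / rowMeans(sg$power)
  b <- sleepkit:::band_def("sigma")
  s_tc <- colSums(npw[sg$freq >= b$lo & sg$freq <= b$hi, ]) * (sg$freq[2] - sg$freq[1])
  # build dF/F as the power time course advanced by 5 s (activity leads power)
  fs_ca <- 20
  n <- 600 * fs_ca
  tt <- (seq_len(n) - 1) / fs_ca
  d_trace <- approx(sg$times - 5, s_tc, xout = tt, rule = 2)$y
  set.seed(8)
  dff <- rbind(d_trace, d_trace, d_trace) +
    matrix(rnorm(3 * n, sd = 0.02 * sd(d_trace)), 3)
  cc <- crosscorr_band_power(dff, fs_ca, sim$recording, sim$hypnogram,
                             labels = rep("RNW", 3), band = "sigma")
  skip_if(length(cc) == 0, "no qualifying NREM bout")
  expect_equal(cc$peaks$lag_s[1], 5, tolerance = 0.75)
  expect_gt(cc$peaks$peak[1], 0.5)
})

test_that("ROI sets round-trip through the labeled-matrix CSV form", {
  s <- small_ca(seed = 21, duration_s = 30)
  p <- tempfile(fileext = ".csv")
  write_roi_masks_csv(s$ca$rois, p)
  r2 <- read_roi_masks_csv(p)
  expect_equal(length(r2$masks), length(s$ca$rois$masks))
  for (k in seq_along(r2$masks))
    expect_equal(r2$masks[[k]], s$ca$rois$masks[[k]])
  expect_equal(r2$vessel, s$ca$rois$vessel)
  expect_equal(r2$off_lens, s$ca$rois$off_lens)
})
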