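# synthetic REM theta trace with phase-continuous frequency steps
theta_trace <- function(dur_s, fs = 1000, f0 = 7.5, events = NULL, f1 = 9,
                        amp = 50, amp_factor = 1.5, noise = 10, seed = 1) {
  set.seed(seed)
  t <- seq(0, dur_s - 1 / fs, by = 1 / fs)
  f <- rep(f0, length(t)); a <- rep(amp, length(t))
  for (i in seq_len(nrow(events %||% data.frame()))) {
    sel <- t >= events$start_s[i] & t < events$end_s[i]
    f[sel] <- f1; a[sel] <- amp * amp_factor
  }
  a * sin(2 * pi * cumsum(f) / fs) + rnorm(length(t), sd = noise)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("trough detection matches the analytic period of a pure tone", {
  fs <- 1000
  x <- sin(2 * pi * 7 * seq(0, 7 - 1 / fs, by = 1 / fs))
  tr <- theta_troughs(x, fs)
  expect_true(abs(length(tr$trough_s) - 49) <= 1)
  iti <- diff(tr$trough_s)
  inner <- iti[2:(length(iti) - 1)]      # first/last cycle touch filter edges
  expect_true(all(abs(inner - 1 / 7) < 0.002))
  # DC has no troughs
  tr0 <- theta_troughs(rep(1, 5000), fs)
  expect_equal(length(tr0$trough_s), 0)
})

test_that("a chirp yields monotonically shrinking smoothed intervals", {
  fs <- 1000
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  f <- 6 + 0.4 * t                       # 6 -> 10 Hz
  x <- sin(2 * pi * cumsum(f) / fs)
  tr <- theta_troughs(x, fs)
  siti <- sleepkit:::smooth_box(diff(tr$trough_s), 11)
  inner <- siti[6:(length(siti) - 5)]    # full 11-point windows only
  expect_true(all(diff(inner) < 1e-5))
})

test_that("constant tonic theta produces no phasic events", {
  x <- theta_trace(120, events = NULL, seed = 3)
  res <- detect_phasic(list(x), 1000)
  expect_equal(nrow(res$events), 0)
})

test_that("injected accelerations are recovered with high recall and precision", {
  ev <- data.frame(start_s = c(20, 55, 90, 130, 170),
                   end_s = c(21.5, 56.5, 91.5, 131.5, 171.5))
  x <- theta_trace(200, events = ev, seed = 5)
  res <- detect_phasic(list(x), 1000)
  m <- match_events(res$events, ev)
  expect_gte(m$recall, 0.8)
  expect_gte(m$precision, 0.8)
  # events are disjoint and inside the episode
  e <- res$events[order(res$events$start_s), ]
  if (nrow(e) > 1) expect_true(all(e$start_s[-1] >= e$end_s[-nrow(e)]))
  expect_true(all(e$start_s >= 0 & e$end_s <= 200))
})

test_that("sub-900 ms candidate runs are rejected by the duration gate", {
  # fixed thresholds so the gates act on constructed runs directly
  thr <- list(pct10_s = 1 / 8.2, pct5_s = 1 / 8.5, mean_rem_amp = 55)
  short <- data.frame(start_s = 30, end_s = 30.8)
  x_short <- theta_trace(60, events = short, seed = 7)
  res_s <- detect_phasic(list(x_short), 1000, thresholds = thr)
  expect_equal(nrow(res_s$events), 0)
  long <- data.frame(start_s = 30, end_s = 31.5)
  x_long <- theta_trace(60, events = long, seed = 7)
  res_l <- detect_phasic(list(x_long), 1000, thresholds = thr)
  expect_equal(nrow(res_l$events), 1)
  expect_gte(res_l$events$duration_s, 0.9)
})

test_that("interval gates are amplitude-invariant; the amplitude gate is covariant", {
  ev <- data.frame(start_s = c(20, 60), end_s = c(21.5, 61.5))
  x <- theta_trace(100, events = ev, seed = 11)
  r1 <- detect_phasic(list(x), 1000)
  r10 <- detect_phasic(list(10 * x), 1000)
  expect_equal(r10$events$start_s, r1$events$start_s, tolerance = 1e-9)
  expect_equal(r10$events$mean_theta_amp, 10 * r1$events$mean_theta_amp,
               tolerance = 1e-4)
  expect_equal(r10$thresholds$pct10_s, r1$thresholds$pct10_s, tolerance = 1e-9)
})

test_that("with fixed thresholds, detection per episode is context-independent", {
  ev <- data.frame(start_s = 20, end_s = 21.5)
  x1 <- theta_trace(60, events = ev, seed = 13)
  x2 <- theta_trace(60, events = NULL, seed = 14)
  thr <- detect_phasic(list(x1, x2), 1000)$thresholds
  together <- detect_phasic(list(x1, x2), 1000, thresholds = thr)$events
  alone <- detect_phasic(list(x1), 1000, thresholds = thr)$events
  expect_equal(together[together$episode_id == 1, c("start_s", "end_s")],
               alone[, c("start_s", "end_s")])
})

test_that("phasic metrics count frequency and contrast tonic vs phasic spectra", {
  cfg <- sim_config(seed = 23, duration_s = 1200)
  sim <- simulate_recording(cfg)
  ph <- phasic_from_recording(sim$recording, sim$hypnogram)
  rem <- ph$rem_episodes
  met <- phasic_metrics(ph$events, rem, rec = sim$recording)
  # 6 events in 3 min would be 2.0/min; here: events over the REM minutes
  expect_equal(met$events_per_min,
               nrow(ph$events) / (sum(rem$duration_s) / 60))
  if (!is.null(met$psd_phasic) && !is.null(met$psd_tonic)) {
    expect_gt(met$peak_freq_hz["phasic"], met$peak_freq_hz["tonic"])
    expect_gt(met$theta_power["phasic"], met$theta_power["tonic"])
  }
})

test_that("episodes with fewer than 11 intervals are skipped with a warning", {
  fs <- 1000
  x <- sin(2 * pi * 7 * seq(0, 1 - 1 / fs, by = 1 / fs))  # ~7 troughs only
  # warns once per skipped episode and once for the empty overall result
  w <- testthat::capture_warnings(res <- detect_phasic(list(x), fs))
  expect_match(w, "fewer than 11", all = FALSE)
  expect_match(w, "empty result", all = FALSE)
  expect_equal(nrow(res$events), 0)
})
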