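rand_trials <- function(n = 20, k = 12, seed = 1, states = c("W", "N", "R")) {
  set.seed(seed)
  matrix(sample(states, n * (k + 1), replace = TRUE), n, k + 1)
}

test_that("constant-state trials give degenerate curves", {
  m <- matrix("N", 10, 13)
  cs <- cumulative_transition(m, "N", "N")
  expect_true(all(cs$prob == 1))
  cr <- cumulative_transition(m, "N", "R")
  expect_true(all(cr$prob == 0))
  # a pair with no onset trials is flagged undefined, not zero
  cw <- cumulative_transition(m, "W", "N")
  expect_true(cw$undefined)
  expect_true(all(is.na(cw$prob)))
})

test_that("hand-built four-trial fixture matches the exhaustive hand count", {
  # N at onset everywhere; two trials transition to R at 20 s and 50 s
  mk <- function(t_r) {
    s <- rep("N", 13)
    if (!is.na(t_r)) s[(t_r / 10 + 1):13] <- "R"
    s
  }
  m <- rbind(mk(20), mk(50), mk(NA), mk(NA))
  cs <- cumulative_transition(m, "N", "R")
  expect_equal(cs$p, 4)
  expect_equal(cs$prob, c(0, 0, 0.25, 0.25, 0.25, 0.5, 0.5, 0.5, 0.5,
                          0.5, 0.5, 0.5, 0.5))
})

test_that("cumulative curves equal the per-trial enumeration oracle", {
  for (s in 1:200) {
    m <- rand_trials(seed = s)
    for (X in c("W", "N", "R")) for (Y in c("W", "N", "R")) {
      got <- cumulative_transition(m, X, Y)
      ora <- oracle_cumulative(m, X, Y)
      expect_equal(got$prob, ora$prob)
      expect_equal(got$p, ora$p)
    }
  }
})

test_that("transition curves are monotone and maintenance anti-monotone", {
  for (s in 1:50) {
    m <- rand_trials(seed = 1000 + s)
    for (X in c("W", "N", "R")) {
      mn <- cumulative_transition(m, X, X)
      if (!mn$undefined) expect_true(all(diff(mn$prob) <= 0))
      for (Y in setdiff(c("W", "N", "R"), X)) {
        cs <- cumulative_transition(m, X, Y)
        if (!cs$undefined) {
          expect_true(all(diff(cs$prob) >= 0))
          expect_true(all(cs$prob >= 0 & cs$prob <= 1))
        }
      }
    }
  }
})

test_that("a fixture that never reaches REM keeps the W->R curve at zero", {
  set.seed(2)
  m <- matrix(sample(c("W", "N"), 15 * 13, replace = TRUE), 15, 13)
  m[, 1] <- "W"
  cs <- cumulative_transition(m, "W", "R")
  expect_true(all(cs$prob == 0))
})

test_that("downsampling commutes with trial alignment", {
  set.seed(9)
  h <- hypnogram(sample(c("W", "N", "R"), 2000, replace = TRUE), epoch_s = 2.5)
  las <- laser_train(c(1000, 2000, 3000), 120)
  # path 1: downsample whole hypnogram, then align
  tr1 <- transition_trials(h, las)
  # path 2: align at 2.5 s, then downsample each trial row
  h10 <- downsample_hypnogram(h, 10)
  for (k in seq_along(las$onsets)) {
    i0 <- floor(las$onsets[k] / 10) + 1
    expect_equal(tr1$laser[k, ], h10$states[i0:(i0 + 12)])
  }
})

test_that("the bootstrap is seed-stable and null on identical intervals", {
  m <- rand_trials(n = 30, seed = 77)
  tr <- structure(list(laser = m, baseline = m, epoch_s = 10, horizon_s = 120,
                       d = seq(0, 120, 10)), class = "transition_trials")
  bt <- bootstrap_transition_test(tr, "N", "R", B = 500, seed = 4)
  expect_true(all(bt$distribution == 0))
  expect_equal(bt$statistic, 0)
  expect_equal(bt$p, 1)
  # seed reproducibility on distinct intervals
  tr2 <- structure(list(laser = rand_trials(n = 30, seed = 78),
                        baseline = rand_trials(n = 30, seed = 79),
                        epoch_s = 10, horizon_s = 120, d = seq(0, 120, 10)),
                   class = "transition_trials")
  b1 <- bootstrap_transition_test(tr2, "N", "R", B = 400, seed = 11)
  b2 <- bootstrap_transition_test(tr2, "N", "R", B = 400, seed = 11)
  expect_identical(b1$distribution, b2$distribution)
  expect_equal(b1$ci, unname(quantile(b1$distribution, c(0.025, 0.975))))
  # doubling B leaves the sign of the mean statistic unchanged
  b4 <- bootstrap_transition_test(tr2, "N", "R", B = 800, seed = 11)
  expect_equal(sign(mean(b4$distribution)), sign(mean(b1$distribution)))
})

test_that("cohort differencing subtracts the per-draw distributions", {
  trA <- structure(list(laser = rand_trials(n = 25, seed = 21),
                        baseline = rand_trials(n = 25, seed = 22),
                        epoch_s = 10, horizon_s = 120, d = seq(0, 120, 10)),
                   class = "transition_trials")
  trB <- structure(list(laser = rand_trials(n = 25, seed = 23),
                        baseline = rand_trials(n = 25, seed = 24),
                        epoch_s = 10, horizon_s = 120, d = seq(0, 120, 10)),
                   class = "transition_trials")
  rA <- bootstrap_transition_test(trA, "N", "R", B = 300, seed = 5)
  rB <- bootstrap_transition_test(trB, "N", "R", B = 300, seed = 6)
  d <- bootstrap_cohort_difference(rA, rB)
  expect_equal(d$distribution, rA$distribution - rB$distribution)
  expect_equal(d$statistic, rA$statistic - rB$statistic)
})

test_that("state percentages partition to 100 and indicate single trials", {
  set.seed(31)
  h <- hypnogram(sample(c("W", "N", "R"), 1500, replace = TRUE))
  las <- laser_train(c(600, 1500), 120)
  tr <- laser_trials(h, las, 120, 120)
  out <- state_percentage_timecourse(tr)
  sums <- out$timecourse$pct_W + out$timecourse$pct_N + out$timecourse$pct_R +
    out$timecourse$pct_U
  expect_true(all(abs(sums - 100) < 1e-9))
  # single trial: the timecourse is an indicator
  tr1 <- laser_trials(h, laser_train(600, 120), 120, 120)
  o1 <- state_percentage_timecourse(tr1)
  vals <- as.matrix(o1$timecourse[, -1])
  expect_true(all(vals %in% c(0, 100)))
})

test_that("laser-interval occupancy matches the chain's stationary occupancy", {
  cfg <- sim_config(seed = 61, duration_s = 4 * 3600)
  onsets <- seq(600, 4 * 3600 - 400, by = 500)
  las <- laser_train(onsets, 120)
  hy <- simulate_hypnogram(cfg, laser = las)   # laser has no effect
  tr <- laser_trials(hy$hypnogram, las, 120, 120)
  out <- state_percentage_timecourse(tr)
  occ_sim <- table(factor(hy$hypnogram$states, c("W", "N", "R"))) /
    length(hy$hypnogram$states)
  las_cols <- out$timecourse$t_s >= 0
  for (s in c("W", "N", "R")) {
    got <- mean(out$timecourse[[paste0("pct_", s)]][las_cols]) / 100
    expect_lt(abs(got - occ_sim[s]), 0.06)
  }
})

test_that("no-effect simulations give ratios near 1; unobserved pairs are omitted", {
  cfg <- sim_config(seed = 71)
  tr <- simulate_transition_trials(cfg, m = 250)
  g <- transition_graph(tr, pairs = data.frame(X = c("N", "N", "R"),
                                               Y = c("R", "W", "W")),
                        B = 400, seed = 2)
  expect_true(all(abs(g$table$ratio - 1) < 0.35))
  expect_gte(min(g$table$p), 0.0)
  # a transition that never occurs in the data is omitted with a note
  set.seed(41)
  m <- matrix(sample(c("W", "N"), 20 * 13, replace = TRUE), 20, 13)
  trWN <- structure(list(laser = m, baseline = m, epoch_s = 10,
                         horizon_s = 120, d = seq(0, 120, 10)),
                    class = "transition_trials")
  g2 <- transition_graph(trWN, pairs = data.frame(X = "N", Y = "R"), B = 200,
                         seed = 3)
  expect_null(g2$table)
  expect_equal(g2$omitted$pair, "N->R")
})

test_that("independent-trial generator is seed-reproducible", {
  cfg <- sim_config(seed = 81)
  t1 <- simulate_transition_trials(cfg, m = 20)
  t2 <- simulate_transition_trials(cfg, m = 20)
  expect_identical(t1$laser, t2$laser)
  expect_identical(t1$baseline, t2$baseline)
})
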