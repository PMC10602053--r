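# Laser-aligned brain-state transition analysis: cumulative transition
# probability curves on a 10 s epoch grid, a trial-resampling bootstrap test
# on the normalized area-under-curve difference between the laser and the
# preceding baseline interval, and the relative-change transition graph.

#' Laser-aligned trial state sequences on the 10 s grid
#'
#' Downsamples the hypnogram to 10 s epochs (majority vote, ties R > N > W)
#' and extracts, per laser trial, the state sequence for the laser interval
#' (t = 0 ... horizon) and the baseline interval (the preceding `horizon_s`
#' re-anchored at its start, whose last step is the onset epoch). Trials
#' truncated at the recording edges are dropped.
#'
#' @param h A `hypnogram` (typically 2.5 s epochs).
#' @param laser A `laser_train`.
#' @param horizon_s Curve horizon (s), default 120.
#' @param epoch_s Analysis epoch (s), default 10.
#' @return List of class `transition_trials`: `laser`, `baseline` (character
#'   matrices, trials x (horizon/epoch + 1); column 1 = state at the anchor),
#'   `epoch_s`, `horizon_s`, `d` (grid 0 ... horizon).
#' @export
transition_trials <- function(h, laser, horizon_s = 120, epoch_s = 10) {
  h10 <- downsample_hypnogram(h, epoch_s)
  k <- horizon_s / epoch_s
  las <- list(); bas <- list()
  for (on in laser$onsets) {
    i0 <- floor((on - h10$t0) / epoch_s) + 1          # epoch containing onset
    iL <- i0:(i0 + k)
    iB <- (i0 - k):i0
    if (iB[1] < 1 || iL[length(iL)] > length(h10$states)) next
    las[[length(las) + 1]] <- h10$states[iL]
    bas[[length(bas) + 1]] <- h10$states[iB]
  }
  if (length(las) == 0) warning("no complete laser trials inside the recording")
  structure(list(laser = do.call(rbind, las), baseline = do.call(rbind, bas),
                 epoch_s = epoch_s, horizon_s = horizon_s,
                 d = seq(0, horizon_s, by = epoch_s)),
            class = "transition_trials")
}

# per-trial cumulative indicator rows for pair X -> Y on a trial matrix:
# row i, column j (d = j*epoch_s): transitioned to Y (or, for X -> X
# maintenance, still continuously in X) within d seconds.
trial_indicators <- function(m, X, Y) {
  k <- ncol(m) - 1
  at_onset <- m[, 1] == X
  ind <- matrix(NA, nrow(m), k)
  for (i in which(at_onset)) {
    s <- m[i, -1]
    ind[i, ] <- if (X == Y) cumprod(s == X) == 1   # maintenance: not yet left
                else cummax(s == Y) == 1           # first entry into Y
  }
  list(at_onset = at_onset, ind = ind)
}

#' Cumulative transition-probability curve from aligned trials
#'
#' P(X -> Y | t <= d) = q / p, where p is the number of trials in state X at
#' the anchor (t = 0) and q the number of those that entered Y within d
#' seconds (first entry, regardless of intervening states). The maintenance
#' curve P(X -> X | t <= d) is the fraction that has not yet left X by d.
#'
#' @param m Character matrix of aligned state sequences (trials x epochs;
#'   column 1 = state at the anchor), e.g. `$laser` of [transition_trials()].
#' @param X,Y State codes.
#' @param epoch_s Epoch length of the grid (s), default 10.
#' @return List: `d` (s), `prob` (curve; starts at 0, or 1 for maintenance),
#'   `p` (trials at onset), `q` (transition counts per d), `undefined`
#'   (TRUE when p = 0; the curve is NA then, never 0).
#' @export
cumulative_transition <- function(m, X, Y, epoch_s = 10) {
  ti <- trial_indicators(m, X, Y)
  p <- sum(ti$at_onset)
  k <- ncol(m) - 1
  d <- seq(0, k * epoch_s, by = epoch_s)
  if (p == 0) {
    return(list(d = d, prob = rep(NA_real_, k + 1), p = 0,
                q = rep(NA_integer_, k), undefined = TRUE))
  }
  q <- colSums(ti$ind[ti$at_onset, , drop = FALSE])
  prob <- c(if (X == Y) 1 else 0, q / p)
  list(d = d, prob = prob, p = p, q = q, undefined = FALSE)
}

#' Baseline and laser curves for one transition pair
#'
#' @param trials A `transition_trials` object.
#' @param X,Y State codes.
#' @return List of class `transition_curve_set`: `pair`, `d`, `baseline`,
#'   `laser` (curve lists from [cumulative_transition()]).
#' @export
transition_curves <- function(trials, X, Y) {
  structure(list(pair = paste0(X, "->", Y), d = trials$d,
                 baseline = cumulative_transition(trials$baseline, X, Y,
                                                  trials$epoch_s),
                 laser = cumulative_transition(trials$laser, X, Y,
                                               trials$epoch_s)),
            class = "transition_curve_set")
}

#' Normalized area under a cumulative transition curve
#'
#' Riemann sum over d = epoch ... horizon, normalized so the full box
#' (probability 1 everywhere) has area 1.
#'
#' @param curve A curve list from [cumulative_transition()].
#' @return Scalar in [0, 1] (NA if the curve is undefined).
#' @export
curve_auc <- function(curve) {
  if (isTRUE(curve$undefined)) return(NA_real_)
  mean(curve$prob[-1])
}

#' Bootstrap test on the laser-baseline AUC difference
#'
#' Resamples the m trials with replacement B times; each draw recomputes the
#' baseline and laser cumulative curves for the pair and takes the normalized
#' AUC difference (laser - baseline). Equal-tail P = 2 min(#{stat <= 0},
#' #{stat >= 0}) / B, reported as `p = 1/B` with `p_below_resolution = TRUE`
#' when one tail is empty. Draws in which no resampled trial is in X at the
#' anchor (for either interval) are redrawn (count logged).
#'
#' @param trials A `transition_trials` object (pool trials across animals).
#' @param X,Y State codes.
#' @param B Bootstrap iterations (default 10000).
#' @param seed Integer seed.
#' @return List of class `bootstrap_result`: `pair`, `statistic` (observed
#'   AUC difference), `distribution` (B draws), `ci` (2.5-97.5 percentile),
#'   `p`, `p_below_resolution`, `B`, `seed`, `n_redraws`, `m`.
#' @export
bootstrap_transition_test <- function(trials, X, Y, B = 10000, seed = 1) {
  m <- nrow(trials$laser)
  if (m < 2) stop("need at least 2 trials")
  tl <- trial_indicators(trials$laser, X, Y)
  tb <- trial_indicators(trials$baseline, X, Y)
  # per-trial normalized AUC contribution (0 for trials not in X at anchor)
  aL <- ifelse(tl$at_onset, rowMeans(tl$ind), 0); aL[is.na(aL)] <- 0
  aB <- ifelse(tb$at_onset, rowMeans(tb$ind), 0); aB[is.na(aB)] <- 0
  xL <- as.numeric(tl$at_onset); xB <- as.numeric(tb$at_onset)
  obs <- sum(aL) / sum(xL) - sum(aB) / sum(xB)
  if (!is.finite(obs)) stop("pair ", X, "->", Y, " unobserved at the anchor")

  set.seed(stage_seed(seed, paste0("boot", X, Y)))
  stat <- numeric(B)
  n_redraws <- 0L
  todo <- seq_len(B)
  while (length(todo) > 0) {
    idx <- matrix(sample.int(m, length(todo) * m, replace = TRUE),
                  nrow = length(todo))
    denL <- rowSums(matrix(xL[idx], nrow(idx))); denB <- rowSums(matrix(xB[idx], nrow(idx)))
    numL <- rowSums(matrix(aL[idx], nrow(idx))); numB <- rowSums(matrix(aB[idx], nrow(idx)))
    ok <- denL > 0 & denB > 0
    stat[todo[ok]] <- numL[ok] / denL[ok] - numB[ok] / denB[ok]
    n_redraws <- n_redraws + sum(!ok)
    todo <- todo[!ok]
  }
  lo <- sum(stat <= 0); hi <- sum(stat >= 0)
  below <- min(lo, hi) == 0
  p <- if (below) 1 / B else min(1, 2 * min(lo, hi) / B)
  structure(list(pair = paste0(X, "->", Y), statistic = obs,
                 distribution = stat,
                 ci = quantile(stat, c(0.025, 0.975), names = FALSE),
                 p = p, p_below_resolution = below, B = B, seed = seed,
                 n_redraws = n_redraws, m = m),
            class = "bootstrap_result")
}

#' Cohort comparison of laser effects
#'
#' Subtracts the per-draw laser-baseline differences of two cohorts'
#' bootstrap results (experimental - control) and derives the CI and
#' equal-tail P from the resulting distribution.
#'
#' @param r_exp,r_ctl `bootstrap_result` objects with equal `B` for the same
#'   transition pair.
#' @return A `bootstrap_result`-like list for the cohort difference.
#' @export
bootstrap_cohort_difference <- function(r_exp, r_ctl) {
  stopifnot(r_exp$B == r_ctl$B)
  d <- r_exp$distribution - r_ctl$distribution
  lo <- sum(d <= 0); hi <- sum(d >= 0)
  below <- min(lo, hi) == 0
  structure(list(pair = r_exp$pair, statistic = r_exp$statistic - r_ctl$statistic,
                 distribution = d,
                 ci = quantile(d, c(0.025, 0.975), names = FALSE),
                 p = if (below) 1 / r_exp$B else min(1, 2 * min(lo, hi) / r_exp$B),
                 p_below_resolution = below, B = r_exp$B),
            class = "bootstrap_result")
}

#' Relative-change transition graph table
#'
#' Per pair: the ratio of laser to baseline curve areas (1 = no change) and
#' the bootstrap significance flag. Pairs never observed at the anchor, or
#' with zero baseline area, are omitted with a note.
#'
#' @param trials A `transition_trials` object.
#' @param pairs Data.frame with columns `X`, `Y` (defaults to the pairs that
#'   occur in the data).
#' @param B,seed Passed to [bootstrap_transition_test()].
#' @param alpha Significance level (default 0.05).
#' @return List: `table` (pair, ratio, p, significant), `omitted`
#'   (data.frame pair, note).
#' @export
transition_graph <- function(trials, pairs = NULL, B = 10000, seed = 1,
                             alpha = 0.05) {
  if (is.null(pairs)) {
    st <- c("W", "N", "R")
    pairs <- expand.grid(X = st, Y = st, stringsAsFactors = FALSE)
  }
  rows <- list(); om <- list()
  for (i in seq_len(nrow(pairs))) {
    X <- pairs$X[i]; Y <- pairs$Y[i]
    cs <- transition_curves(trials, X, Y)
    if (cs$laser$undefined || cs$baseline$undefined) {
      om[[length(om) + 1]] <- data.frame(pair = cs$pair,
                                         note = "state not observed at anchor")
      next
    }
    if (X != Y && sum(cs$laser$q[length(cs$laser$q)],
                      cs$baseline$q[length(cs$baseline$q)]) == 0) {
      om[[length(om) + 1]] <- data.frame(pair = cs$pair,
                                         note = "transition never observed")
      next
    }
    auc_b <- curve_auc(cs$baseline); auc_l <- curve_auc(cs$laser)
    if (auc_b == 0) {
      om[[length(om) + 1]] <- data.frame(pair = cs$pair,
                                         note = "zero baseline area; ratio undefined")
      next
    }
    bt <- bootstrap_transition_test(trials, X, Y, B = B, seed = seed)
    rows[[length(rows) + 1]] <- data.frame(pair = cs$pair, ratio = auc_l / auc_b,
                                           p = bt$p, significant = bt$p < alpha)
  }
  list(table = if (length(rows) > 0) do.call(rbind, rows) else NULL,
       omitted = if (length(om) > 0) do.call(rbind, om) else NULL)
}

#' Brain-state percentage time course around laser onset
#'
#' At each aligned time point, the percentage of trials in each state
#' (W/N/R percentages sum to 100 when no epoch is undefined). Also returns
#' per-trial mean percentages over the laser interval and the preceding
#' equal-length baseline, the summary consumed by paired tests across
#' animals.
#'
#' @param trials Output of [laser_trials()] (2.5 s aligned states).
#' @param laser_duration_s Laser interval length (s), default 120.
#' @return List: `timecourse` (data.frame t_s, pct_W, pct_N, pct_R, pct_U),
#'   `trial_means` (data.frame trial, state, baseline_pct, laser_pct).
#' @export
state_percentage_timecourse <- function(trials, laser_duration_s = 120) {
  m <- trials$states
  tc <- data.frame(t_s = trials$t)
  for (s in brain_states())
    tc[[paste0("pct_", s)]] <- colMeans(m == s) * 100
  las <- trials$t >= 0 & trials$t < laser_duration_s
  bas <- trials$t >= -laser_duration_s & trials$t < 0
  rows <- list()
  for (i in seq_len(nrow(m))) {
    for (s in c("W", "N", "R")) {
      rows[[length(rows) + 1]] <- data.frame(
        trial = i, state = s,
        baseline_pct = mean(m[i, bas] == s) * 100,
        laser_pct = mean(m[i, las] == s) * 100)
    }
  }
  list(timecourse = tc, trial_means = do.call(rbind, rows))
}
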