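# Shared helpers for the test suite. All fixtures are generated in code.

# interval overlap in seconds
interval_overlap <- function(a0, a1, b0, b1) {
  pmax(0, pmin(a1, b1) - pmax(a0, b0))
}

# match detected events against ledger intervals: a ledger event is hit when
# a detection covers at least `frac` of the shorter of the two intervals
match_events <- function(det, truth, frac = 0.5) {
  hit_truth <- rep(FALSE, nrow(truth))
  hit_det <- rep(FALSE, nrow(det))
  for (i in seq_len(nrow(truth))) {
    for (j in seq_len(nrow(det))) {
      ov <- interval_overlap(truth$start_s[i], truth$end_s[i],
                             det$start_s[j], det$end_s[j])
      shorter <- min(truth$end_s[i] - truth$start_s[i],
                     det$end_s[j] - det$start_s[j])
      if (shorter > 0 && ov >= frac * shorter) {
        hit_truth[i] <- TRUE
        hit_det[j] <- TRUE
      }
    }
  }
  list(recall = if (nrow(truth) > 0) mean(hit_truth) else NA_real_,
       precision = if (nrow(det) > 0) mean(hit_det) else NA_real_)
}

# brute-force cumulative transition curve: literal per-trial enumeration
oracle_cumulative <- function(m, X, Y, epoch_s = 10) {
  k <- ncol(m) - 1
  rows <- which(m[, 1] == X)
  p <- length(rows)
  if (p == 0) return(list(prob = rep(NA_real_, k + 1), p = 0))
  prob <- numeric(k + 1)
  prob[1] <- if (X == Y) 1 else 0
  for (j in seq_len(k)) {
    q <- 0
    for (i in rows) {
      s <- m[i, 2:(j + 1)]
      ok <- if (X == Y) all(s == X) else any(s == Y)
      q <- q + ok
    }
    prob[j + 1] <- q / p
  }
  list(prob = prob, p = p)
}

# brute-force burst grouping: transitive closure of the pairwise relation
# "adjacent in time with gap < gap_s", via repeated pairwise merging
oracle_bursts <- function(t, gap_s = 0.25) {
  t <- sort(t)
  n <- length(t)
  if (n == 0) return(integer(0))
  grp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n - 1)) for (j in seq_len(n)[-i]) {
      if (abs(t[j] - t[i]) < gap_s && grp[j] != grp[i]) {
        grp[grp == grp[j]] <- grp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(grp, unique(grp))
}

# literal three-loop activity map (same definition as activity_map)
oracle_activity_map <- function(movie) {
  d <- dim(movie)
  fbar <- matrix(0, d[1], d[2])
  for (x in 1:d[1]) for (y in 1:d[2]) fbar[x, y] <- mean(movie[x, y, ])
  favg <- mean(movie)
  M <- matrix(0, d[1], d[2])
  for (t in 1:d[3]) {
    dev <- (movie[, , t] - fbar) / (fbar + favg)
    sm <- matrix(0, d[1], d[2])
    for (x in 1:d[1]) for (y in 1:d[2]) {
      # 2x2 box over the pixel and its +x/+y neighbours, clamped at edges
      sm[x, y] <- (dev[x, y] + dev[min(x + 1, d[1]), y] +
                   dev[x, min(y + 1, d[2])] +
                   dev[min(x + 1, d[1]), min(y + 1, d[2])]) / 4
    }
    M <- M + abs(sm)
  }
  M / d[3]
}

quiet <- function(expr) suppressWarnings(suppressMessages(expr))
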