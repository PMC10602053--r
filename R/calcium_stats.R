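# Statistics on calcium traces: brain-state subclass classification,
# transition-aligned activity, phasic-event contrasts, and cross-correlation
# with EEG band power.

#' Mean dF/F per hypnogram epoch
#'
#' @param dff Matrix (cells x frames) or numeric vector.
#' @param h A `hypnogram`.
#' @param fs Frame rate of `dff` (Hz).
#' @return List: `means` (cells x epochs), `state` (per epoch).
#' @export
epoch_means <- function(dff, h, fs) {
  if (is.null(dim(dff))) dff <- matrix(dff, 1)
  n <- ncol(dff)
  ep <- pmin(floor(((seq_len(n) - 1) / fs) / h$epoch_s) + 1, length(h$states))
  K <- length(h$states)
  counts <- tabulate(ep, K)
  sums <- t(apply(dff, 1, function(x) {
    s <- numeric(K); tmp <- tapply(x, ep, sum)
    s[as.integer(names(tmp))] <- tmp; s
  }))
  keep <- counts > 0
  list(means = sweep(sums[, keep, drop = FALSE], 2, counts[keep], "/"),
       state = h$states[keep])
}

#' Classify cells into brain-state subclasses
#'
#' Per cell, a one-way ANOVA of epoch-mean dF/F across wake, NREM and REM
#' decides whether the cell is state-modulated (P < alpha). For modulated
#' cells, Tukey's HSD establishes the state of maximal activity: the
#' top-mean state must differ significantly from both other states, otherwise
#' the cell stays unmodulated. REM-max cells are split into R>N>W (`"RNW"`)
#' vs R>W>N (`"RWN"`) by their NREM vs wake means; the other labels are
#' `"Wmax"`, `"Nmax"` and `"unmod"`.
#'
#' @param dff Matrix (cells x frames).
#' @param h The `hypnogram`.
#' @param fs Frame rate (Hz).
#' @param alpha Significance level (default 0.05).
#' @return List: `table` (cell, p_anova, label), `proportions` (over
#'   modulated cells), `n_modulated`.
#' @export
classify_subclasses <- function(dff, h, fs, alpha = 0.05) {
  em <- epoch_means(dff, h, fs)
  sel <- em$state %in% c("W", "N", "R")
  st <- factor(em$state[sel], levels = c("W", "N", "R"))
  for (s in c("W", "N", "R")) {
    if (!any(st == s))
      stop("state ", s, " absent from the session; cannot classify")
  }
  K <- nrow(em$means)
  labs <- character(K); pvals <- numeric(K)
  for (k in seq_len(K)) {
    y <- em$means[k, sel]
    fit <- aov(y ~ st)
    pvals[k] <- summary(fit)[[1]][["Pr(>F)"]][1]
    if (is.na(pvals[k]) || pvals[k] >= alpha) { labs[k] <- "unmod"; next }
    mns <- tapply(y, st, mean)
    top <- names(mns)[which.max(mns)]
    tk <- TukeyHSD(fit)$st
    pair_p <- function(a, b) {
      nm <- rownames(tk)
      i <- match(paste0(a, "-", b), nm)
      if (is.na(i)) i <- match(paste0(b, "-", a), nm)
      tk[i, "p adj"]
    }
    others <- setdiff(c("W", "N", "R"), top)
    confirmed <- all(vapply(others, function(o) pair_p(top, o) < alpha, logical(1)))
    labs[k] <- if (!confirmed) "unmod"
               else switch(top,
                           R = if (mns["N"] > mns["W"]) "RNW" else "RWN",
                           W = "Wmax", N = "Nmax")
  }
  mod <- labs != "unmod"
  props <- if (any(mod)) table(labs[mod]) / sum(mod) else table(character(0))
  list(table = data.frame(cell = seq_len(K), p_anova = pvals, label = labs),
       proportions = props, n_modulated = sum(mod))
}

# transitions X -> Y in a hypnogram that satisfy the preceding-episode rules:
# NREM or wake episodes must last >= 60 s before the transition (NREM may be
# interrupted by microarousals); REM before REM -> Wake must last >= 10 s.
qualifying_transitions <- function(h, X, Y, min_pre_s = NULL,
                                   bridge_microarousal_s = 10) {
  if (is.null(min_pre_s)) min_pre_s <- if (X == "R") 10 else 60
  eps <- episodes(h, X, bridge_microarousal_s =
                    if (X == "N") bridge_microarousal_s else 0)
  out <- numeric(0)
  for (i in seq_len(nrow(eps))) {
    if (eps$duration_s[i] < min_pre_s) next
    nxt <- state_at(h, eps$end_s[i] + h$epoch_s / 2)
    if (!is.na(nxt) && nxt == Y) out <- c(out, eps$end_s[i])
  }
  out
}

#' Transition-aligned subclass activity
#'
#' Aligns z-scored dF/F (z over the full recording per cell) at qualifying
#' X -> Y transitions, averages per cell in 10 s bins over the window, then
#' per subclass: a repeated-measures ANOVA (cells as subjects, bins as the
#' within factor) gates Holm-corrected paired t-tests of each bin against the
#' first (baseline) bin.
#'
#' @param dff Matrix (cells x frames).
#' @param h The `hypnogram`.
#' @param fs Frame rate (Hz).
#' @param labels Subclass label per cell (e.g. from [classify_subclasses()]).
#' @param X,Y Transition pair (state codes).
#' @param window_s `c(pre, post)` seconds around the transition, default
#'   `c(-60, 30)`.
#' @param bin_s Bin width (s), default 10.
#' @param alpha Significance level.
#' @return List per subclass: `bins` (centers, s), `mean`, `sem` (per bin),
#'   `p_rm_anova`, `sig_bins` (logical per bin; baseline bin FALSE),
#'   `n_cells`, `n_transitions`; plus `transition_times_s`.
#' @export
align_to_transitions <- function(dff, h, fs, labels, X, Y,
                                 window_s = c(-60, 30), bin_s = 10,
                                 alpha = 0.05) {
  tr <- qualifying_transitions(h, X, Y)
  nb <- round((window_s[2] - window_s[1]) / bin_s)
  if (length(tr) == 0) {
    warning("no qualifying ", X, "->", Y, " transitions")
    return(list(subclasses = list(), transition_times_s = numeric(0)))
  }
  z <- t(apply(dff, 1, function(x) (x - mean(x)) / sd(x)))
  n <- ncol(z)
  edges <- seq(window_s[1], window_s[2], by = bin_s)
  per_cell <- array(NA_real_, dim = c(nrow(z), nb, length(tr)))
  used <- logical(length(tr))
  for (ti in seq_along(tr)) {
    i0 <- floor((tr[ti] + window_s[1]) * fs) + 1
    i1 <- floor((tr[ti] + window_s[2]) * fs)
    if (i0 < 1 || i1 > n) next
    used[ti] <- TRUE
    for (b in seq_len(nb)) {
      j0 <- floor((tr[ti] + edges[b]) * fs) + 1
      j1 <- floor((tr[ti] + edges[b + 1]) * fs)
      per_cell[, b, ti] <- rowMeans(z[, j0:j1, drop = FALSE])
    }
  }
  if (!any(used)) {
    warning("all ", X, "->", Y, " transitions truncated at recording edges")
    return(list(subclasses = list(), transition_times_s = numeric(0)))
  }
  cell_bins <- apply(per_cell[, , used, drop = FALSE], c(1, 2), mean)
  out <- list()
  for (lab in unique(labels)) {
    cells <- which(labels == lab)
    if (length(cells) < 2) next
    m <- cell_bins[cells, , drop = FALSE]
    dat <- data.frame(y = as.numeric(m),
                      cell = factor(rep(cells, nb)),
                      bin = factor(rep(seq_len(nb), each = length(cells))))
    fit <- aov(y ~ bin + Error(cell), data = dat)
    p_rm <- summary(fit)[["Error: Within"]][[1]][["Pr(>F)"]][1]
    sig <- rep(FALSE, nb)
    if (!is.na(p_rm) && p_rm < alpha) {
      pt <- vapply(2:nb, function(b)
        t.test(m[, b], m[, 1], paired = TRUE)$p.value, numeric(1))
      sig[2:nb] <- p.adjust(pt, method = "holm") < alpha
    }
    out[[lab]] <- list(bins = edges[-1] - bin_s / 2,
                       mean = colMeans(m),
                       sem = apply(m, 2, sd) / sqrt(nrow(m)),
                       p_rm_anova = p_rm, sig_bins = sig,
                       n_cells = nrow(m), n_transitions = sum(used))
  }
  list(subclasses = out, transition_times_s = tr[used])
}

#' Time-normalized activity across NREM -> REM -> Wake sequences
#'
#' Each NREM, REM and wake episode of a qualifying sequence is divided into a
#' fixed number of bins and the per-cell z-scored dF/F averaged per bin, so
#' sequences of different durations are comparable. REM episodes are split
#' into short (< `rem_split_s`) and long (>= `rem_split_s`).
#'
#' @param dff Matrix (cells x frames).
#' @param h The `hypnogram`.
#' @param fs Frame rate (Hz).
#' @param labels Subclass label per cell.
#' @param n_bins Bins per episode (default 10).
#' @param rem_split_s Short/long REM cut (default 30 s).
#' @return Per subclass and REM-duration class: mean curve over the 3 x
#'   `n_bins` normalized bins (+ `n_sequences`).
#' @export
time_normalized_nrw <- function(dff, h, fs, labels, n_bins = 10,
                                rem_split_s = 30) {
  rem <- episodes(h, "R", bridge_microarousal_s = 0)
  z <- t(apply(dff, 1, function(x) (x - mean(x)) / sd(x)))
  n <- ncol(z)
  seqs <- list()
  for (i in seq_len(nrow(rem))) {
    pre <- state_at(h, rem$start_s[i] - h$epoch_s / 2)
    post <- state_at(h, rem$end_s[i] + h$epoch_s / 2)
    if (is.na(pre) || is.na(post) || pre != "N" || post != "W") next
    n_ep <- episodes(h, "N", bridge_microarousal_s = 10)
    w_ep <- episodes(h, "W", bridge_microarousal_s = 0)
    nprev <- n_ep[abs(n_ep$end_s - rem$start_s[i]) < h$epoch_s / 2, ]
    wnext <- w_ep[abs(w_ep$start_s - rem$end_s[i]) < h$epoch_s / 2, ]
    if (nrow(nprev) != 1 || nrow(wnext) != 1) next
    seqs[[length(seqs) + 1]] <- list(
      bounds = rbind(c(nprev$start_s, nprev$end_s),
                     c(rem$start_s[i], rem$end_s[i]),
                     c(wnext$start_s, wnext$end_s)),
      rem_dur = rem$duration_s[i])
  }
  curve_of <- function(sq) {
    vals <- matrix(NA_real_, nrow(z), 3 * n_bins)
    for (epi in 1:3) {
      e <- seq(sq$bounds[epi, 1], sq$bounds[epi, 2], length.out = n_bins + 1)
      for (b in seq_len(n_bins)) {
        j0 <- max(1, floor(e[b] * fs) + 1); j1 <- min(n, ceiling(e[b + 1] * fs))
        vals[, (epi - 1) * n_bins + b] <- rowMeans(z[, j0:j1, drop = FALSE])
      }
    }
    vals
  }
  out <- list()
  for (cls in c("short", "long")) {
    sel <- Filter(function(sq)
      (cls == "short") == (sq$rem_dur < rem_split_s), seqs)
    if (length(sel) == 0) next
    stacks <- lapply(sel, curve_of)
    cell_curve <- Reduce(`+`, stacks) / length(stacks)
    out[[cls]] <- lapply(split(seq_along(labels), labels), function(cells) {
      list(mean = colMeans(cell_curve[cells, , drop = FALSE]),
           n_sequences = length(sel), n_cells = length(cells))
    })
  }
  out
}

#' Subclass activity during phasic theta events
#'
#' Per cell: mean dF/F inside each phasic event versus the immediately
#' preceding tonic interval of equal duration (events with no room for the
#' baseline inside their REM episode are skipped). Per subclass, a paired
#' t-test across cells compares event vs baseline means.
#'
#' @param dff Matrix (cells x frames).
#' @param fs Frame rate (Hz).
#' @param events Phasic event table (`start_s`, `end_s`, `episode_id`).
#' @param rem_eps REM episode table from [episodes()].
#' @param labels Subclass label per cell.
#' @return List per subclass: `mean_event`, `mean_baseline`, `t`, `p`,
#'   `n_cells`, `n_events`.
#' @export
phasic_event_activity <- function(dff, fs, events, rem_eps, labels) {
  n <- ncol(dff)
  ev_means <- list(); bl_means <- list()
  n_used <- 0
  for (i in seq_len(nrow(events))) {
    d <- events$end_s[i] - events$start_s[i]
    b0 <- events$start_s[i] - d
    ep <- rem_eps[rem_eps$episode_id == events$episode_id[i], ]
    if (nrow(ep) == 1 && b0 < ep$start_s) next   # no room for baseline
    je <- (floor(events$start_s[i] * fs) + 1):min(n, floor(events$end_s[i] * fs))
    jb <- (floor(b0 * fs) + 1):floor(events$start_s[i] * fs)
    if (jb[1] < 1) next
    n_used <- n_used + 1
    ev_means[[n_used]] <- rowMeans(dff[, je, drop = FALSE])
    bl_means[[n_used]] <- rowMeans(dff[, jb, drop = FALSE])
  }
  if (n_used == 0) {
    warning("no phasic events with a valid baseline interval")
    return(list())
  }
  ev <- rowMeans(do.call(cbind, ev_means))
  bl <- rowMeans(do.call(cbind, bl_means))
  out <- list()
  for (lab in unique(labels)) {
    cells <- which(labels == lab)
    if (length(cells) < 3) next
    tt <- t.test(ev[cells], bl[cells], paired = TRUE)
    out[[lab]] <- list(mean_event = mean(ev[cells]),
                       mean_baseline = mean(bl[cells]),
                       t = unname(tt$statistic), p = tt$p.value,
                       n_cells = length(cells), n_events = n_used)
  }
  out
}

#' Cross-correlation between dF/F and an EEG power band
#'
#' For NREM bouts of at least `min_bout_s` (microarousal-bridged), the band
#' power is taken from a 2.5 s / 80 %-overlap spectrogram (0.5 s grid) with
#' each frequency component normalized by its recording mean, and the dF/F
#' downsampled onto the same grid. The cross-correlation (demeaned, divided
#' by sd(s) sd(d) N) is averaged over bouts; per cell, the maximum-magnitude
#' peak in +-`max_lag_s` is located (positive lag = dF/F leads the power),
#' and per subclass a one-sample t-test checks the peak values against 0.
#'
#' @param dff Matrix (cells x frames).
#' @param fs_ca Frame rate of `dff` (Hz).
#' @param rec A `signal_recording`.
#' @param h The `hypnogram`.
#' @param labels Subclass label per cell.
#' @param band Band name or `c(lo, hi)` Hz (default `"sigma"`).
#' @param channel EEG channel.
#' @param min_bout_s Minimum NREM bout length (default 120).
#' @param max_lag_s Peak search range (default 30).
#' @return List: `lags_s`, `cc` (cells x lags, bout-averaged), `peaks`
#'   (data.frame cell, peak, lag_s), `tests` (per subclass: t, p, n).
#' @export
crosscorr_band_power <- function(dff, fs_ca, rec, h, labels, band = "sigma",
                                 channel = "EEG_parietal", min_bout_s = 120,
                                 max_lag_s = 30) {
  bouts <- episodes(h, "N", bridge_microarousal_s = 10)
  bouts <- bouts[bouts$duration_s >= min_bout_s, , drop = FALSE]
  if (nrow(bouts) == 0) {
    warning("no NREM bout of at least ", min_bout_s, " s")
    return(list())
  }
  sg <- spectrogram(get_channel(rec, channel), rec$fs,
                    window_s = 2.5, step_s = 0.5, psd_window_s = 2)
  npow <- sg$power / rowMeans(sg$power)
  b <- band_def(band)
  dfq <- sg$freq[2] - sg$freq[1]
  s_full <- colSums(npow[sg$freq >= b$lo & sg$freq <= b$hi, , drop = FALSE]) * dfq
  # dF/F on the same 0.5 s window grid
  nfr <- ncol(dff)
  d_full <- vapply(seq_along(sg$times), function(j) {
    j0 <- max(1, floor((sg$times[j] - 1.25) * fs_ca) + 1)
    j1 <- min(nfr, ceiling((sg$times[j] + 1.25) * fs_ca))
    rowMeans(dff[, j0:j1, drop = FALSE])
  }, numeric(nrow(dff)))
  if (is.null(dim(d_full))) d_full <- matrix(d_full, 1)

  kmax <- round(max_lag_s / 0.5)
  lags <- (-kmax:kmax) * 0.5
  acc <- matrix(0, nrow(dff), length(lags)); nb <- 0
  for (i in seq_len(nrow(bouts))) {
    sel <- which(sg$times - 1.25 >= bouts$start_s[i] &
                 sg$times + 1.25 <= bouts$end_s[i])
    if (length(sel) < 2 * kmax + 10) next
    s <- s_full[sel]; s <- s - mean(s)
    D <- d_full[, sel, drop = FALSE]
    D <- D - rowMeans(D)
    Ns <- length(s)
    cc_b <- matrix(0, nrow(dff), length(lags))
    for (li in seq_along(lags)) {
      k <- li - kmax - 1   # lag in steps; positive: dff leads power
      if (k >= 0) {
        ss <- s[(1 + k):Ns]; DD <- D[, 1:(Ns - k), drop = FALSE]
      } else {
        ss <- s[1:(Ns + k)]; DD <- D[, (1 - k):Ns, drop = FALSE]
      }
      cc_b[, li] <- (DD %*% ss) / (sd(s) * apply(D, 1, sd) * Ns)
    }
    acc <- acc + cc_b; nb <- nb + 1
  }
  if (nb == 0) {
    warning("no NREM bout long enough for the lag range")
    return(list())
  }
  cc <- acc / nb
  pk_i <- apply(abs(cc), 1, which.max)
  peaks <- data.frame(cell = seq_len(nrow(cc)),
                      peak = cc[cbind(seq_len(nrow(cc)), pk_i)],
                      lag_s = lags[pk_i])
  tests <- list()
  for (lab in unique(labels)) {
    cells <- which(labels == lab)
    if (length(cells) < 3) next
    tt <- tryCatch(t.test(peaks$peak[cells]), error = function(e) NULL)
    tests[[lab]] <- list(t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
                         p = if (is.null(tt)) NA_real_ else tt$p.value,
                         n = length(cells))
  }
  list(lags_s = lags, cc = cc, peaks = peaks, tests = tests, n_bouts = nb)
}
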