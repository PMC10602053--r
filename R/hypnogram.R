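#' Brain-state codes
#'
#' The four-state vocabulary used throughout the package: `"W"` (wake), `"N"`
#' (NREM sleep), `"R"` (REM sleep) and `"U"` (undefined/artifact). `"U"` epochs
#' never enter statistics.
#'
#' @return Character vector of the four valid single-letter codes.
#' @export
brain_states <- function() c("W", "N", "R", "U")

assert_states <- function(states) {
  bad <- setdiff(unique(states), brain_states())
  if (length(bad) > 0) {
    stop("unknown brain-state code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(states)
}

#' Construct a hypnogram
#'
#' A hypnogram is a sequence of brain states on a uniform epoch grid. The
#' default 2.5 s epoch matches the half-overlapping 5 s spectrogram windows
#' used for scoring.
#'
#' @param states Character vector of state codes (`W`/`N`/`R`/`U`).
#' @param epoch_s Epoch length in seconds (> 0).
#' @param t0 Start time of the first epoch in seconds.
#' @return An object of class `hypnogram`: list with `states`, `epoch_s`, `t0`.
#' @export
hypnogram <- function(states, epoch_s = 2.5, t0 = 0) {
  states <- as.character(states)
  if (length(states) < 1) stop("hypnogram needs at least one epoch")
  if (!is.numeric(epoch_s) || epoch_s <= 0) stop("epoch_s must be > 0")
  assert_states(states)
  structure(list(states = states, epoch_s = epoch_s, t0 = t0),
            class = "hypnogram")
}

#' @export
length.hypnogram <- function(x) length(x$states)

#' @export
print.hypnogram <- function(x, ...) {
  tab <- table(factor(x$states, levels = brain_states()))
  cat(sprintf("hypnogram: %d epochs x %.3g s (%.1f s total)\n",
              length(x$states), x$epoch_s, length(x$states) * x$epoch_s))
  cat(sprintf("  W %d | N %d | R %d | U %d\n",
              tab["W"], tab["N"], tab["R"], tab["U"]))
  invisible(x)
}

#' Epoch start times of a hypnogram
#' @param h A `hypnogram`.
#' @return Numeric vector of epoch start times (seconds).
#' @export
epoch_times <- function(h) h$t0 + (seq_along(h$states) - 1) * h$epoch_s

#' State at given times
#'
#' Looks up the brain state of the epoch containing each time point (epochs
#' are half-open intervals `[t, t + epoch_s)`). Times outside the hypnogram
#' return `NA`.
#'
#' @param h A `hypnogram`.
#' @param t Numeric vector of times in seconds.
#' @return Character vector of state codes (`NA` outside the record).
#' @export
state_at <- function(h, t) {
  idx <- floor((t - h$t0) / h$epoch_s) + 1
  out <- rep(NA_character_, length(t))
  ok <- idx >= 1 & idx <= length(h$states)
  out[ok] <- h$states[idx[ok]]
  out
}

#' Read a hypnogram from a plain-text file
#'
#' Format: a header line `epoch_s=<seconds>` (optionally also `t0=<seconds>`),
#' then one single-letter state code per line.
#'
#' @param path File path.
#' @return A `hypnogram`.
#' @export
read_hypnogram <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) stop("empty hypnogram file: ", path)
  hdr <- grep("^\\s*[a-zA-Z_0-9]+\\s*=", lines)
  meta <- list(epoch_s = 2.5, t0 = 0)
  for (i in hdr) {
    kv <- strsplit(sub("^\\s+|\\s+$", "", lines[i]), "=")[[1]]
    meta[[trimws(kv[1])]] <- as.numeric(kv[2])
  }
  body_idx <- setdiff(seq_along(lines), hdr)
  body_idx <- body_idx[nzchar(trimws(lines[body_idx]))]
  states <- trimws(lines[body_idx])
  bad <- which(!states %in% brain_states())
  if (length(bad) > 0) {
    stop(sprintf("unknown state code '%s' at line %d of %s",
                 states[bad[1]], body_idx[bad[1]], path), call. = FALSE)
  }
  hypnogram(states, epoch_s = meta$epoch_s, t0 = meta$t0)
}

#' Write a hypnogram to a plain-text file
#' @param h A `hypnogram`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_hypnogram <- function(h, path) {
  writeLines(c(sprintf("epoch_s=%.10g", h$epoch_s),
               sprintf("t0=%.10g", h$t0),
               h$states), path)
  invisible(path)
}

#' Segment a hypnogram into episodes of one state
#'
#' Returns the maximal runs of `state`. For NREM, wake interruptions no longer
#' than `bridge_microarousal_s` (microarousals) are bridged: the flanking NREM
#' runs are merged into one episode whose duration includes the gap, and the
#' gap epochs are flagged in `microarousal_mask`. Bridging is an analysis-time
#' convention; the stored hypnogram is never modified.
#'
#' @param h A `hypnogram`.
#' @param state State code to segment (`"W"`, `"N"` or `"R"`).
#' @param bridge_microarousal_s Maximum wake-gap duration (seconds) bridged
#'   when `state == "N"`. Default 10 s. Use 0 to disable.
#' @return A data.frame with one row per episode: `state`, `start_s`, `end_s`,
#'   `duration_s`, `n_ma_epochs`, and a list-column `microarousal_mask`
#'   (logical per epoch of the episode).
#' @export
episodes <- function(h, state, bridge_microarousal_s = 10) {
  stopifnot(bridge_microarousal_s >= 0)
  assert_states(state)
  s <- h$states
  r <- rle(s)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- data.frame(value = r$values, start = starts, end = ends)
  keep <- runs$value == state
  if (!any(keep)) {
    return(empty_episode_table())
  }
  idx <- which(keep)
  # bridging: merge consecutive `state` runs separated by a single short W run
  groups <- list(idx[1])
  if (state == "N" && bridge_microarousal_s > 0 && length(idx) > 1) {
    for (k in idx[-1]) {
      prev <- groups[[length(groups)]]
      between <- runs[(prev[length(prev)] + 1):(k - 1), , drop = FALSE]
      gap_ok <- nrow(between) == 1 && between$value == "W" &&
        (between$end - between$start + 1) * h$epoch_s <= bridge_microarousal_s
      if (gap_ok) {
        groups[[length(groups)]] <- c(prev, k)
      } else {
        groups[[length(groups) + 1]] <- k
      }
    }
  } else {
    groups <- as.list(idx)
  }
  out <- lapply(groups, function(g) {
    e_start <- runs$start[g[1]]
    e_end <- runs$end[g[length(g)]]
    mask <- h$states[e_start:e_end] != state
    data.frame(state = state,
               start_s = h$t0 + (e_start - 1) * h$epoch_s,
               end_s = h$t0 + e_end * h$epoch_s,
               duration_s = (e_end - e_start + 1) * h$epoch_s,
               n_ma_epochs = sum(mask))
  })
  tab <- do.call(rbind, out)
  tab$microarousal_mask <- lapply(groups, function(g) {
    h$states[runs$start[g[1]]:runs$end[g[length(g)]]] != state
  })
  tab$episode_id <- seq_len(nrow(tab))
  tab
}

empty_episode_table <- function() {
  tab <- data.frame(state = character(0), start_s = numeric(0),
                    end_s = numeric(0), duration_s = numeric(0),
                    n_ma_epochs = integer(0))
  tab$microarousal_mask <- list()
  tab$episode_id <- integer(0)
  tab
}

#' Laser-aligned trial table
#'
#' Aligns the hypnogram at each laser onset and returns the per-trial state
#' sequence from `pre_s` before to `post_s` after the onset, together with the
#' state at t = 0 (the alignment/sorting key of trial rasters). Trials that
#' would be truncated at the recording edges are dropped.
#'
#' @param h A `hypnogram`.
#' @param laser A `laser_train` (see [laser_train()]).
#' @param pre_s,post_s Seconds before/after the onset (>= 0).
#' @return List with `states` (matrix: trials x epochs), `t` (epoch start
#'   times relative to onset), `onset_s`, `state_at_onset`.
#' @export
laser_trials <- function(h, laser, pre_s = 120, post_s = 120) {
  stopifnot(pre_s >= 0, post_s >= 0)
  n_pre <- round(pre_s / h$epoch_s)
  n_post <- round(post_s / h$epoch_s)
  rel <- seq(-n_pre, n_post - 1) * h$epoch_s
  rows <- list(); onsets <- numeric(0)
  for (on in laser$onsets) {
    t_abs <- on + rel
    st <- state_at(h, t_abs)
    if (anyNA(st)) next   # truncated at recording edge
    rows[[length(rows) + 1]] <- st
    onsets <- c(onsets, on)
  }
  if (length(rows) == 0) {
    warning("no laser trials fall fully inside the recording")
    return(list(states = matrix(character(0), 0, n_pre + n_post), t = rel,
                onset_s = numeric(0), state_at_onset = character(0)))
  }
  m <- do.call(rbind, rows)
  colnames(m) <- sprintf("%+.1fs", rel)
  list(states = m, t = rel, onset_s = onsets,
       state_at_onset = m[, n_pre + 1])
}

#' Construct a laser stimulation train
#'
#' @param onsets Strictly increasing onset times (seconds).
#' @param duration_s Trial duration in seconds (scalar or per-trial vector).
#' @param mode `"open_loop"` or `"closed_loop"`.
#' @return An object of class `laser_train`.
#' @export
laser_train <- function(onsets, duration_s, mode = c("open_loop", "closed_loop")) {
  mode <- match.arg(mode)
  dur <- rep_len(duration_s, length(onsets))
  if (length(onsets) > 1) {
    if (any(diff(onsets) <= 0)) stop("laser onsets must be strictly increasing")
    if (any(onsets[-1] < onsets[-length(onsets)] + dur[-length(onsets)]))
      stop("laser trials must not overlap")
  }
  structure(list(onsets = onsets, duration_s = dur, mode = mode),
            class = "laser_train")
}

#' Read / write a laser train as CSV (columns onset_s, duration_s)
#' @param path CSV path.
#' @param mode Stimulation mode stored on the object.
#' @return A `laser_train`.
#' @export
read_laser_train <- function(path, mode = "open_loop") {
  d <- read.csv(path)
  laser_train(d$onset_s, d$duration_s, mode = mode)
}

#' @rdname read_laser_train
#' @param laser A `laser_train`.
#' @export
write_laser_train <- function(laser, path) {
  write.csv(data.frame(onset_s = laser$onsets, duration_s = laser$duration_s),
            path, row.names = FALSE)
  invisible(path)
}

#' Is each time point inside a laser interval?
#' @param laser A `laser_train`.
#' @param t Numeric vector of times (seconds).
#' @return Logical vector.
#' @export
in_laser <- function(laser, t) {
  out <- rep(FALSE, length(t))
  for (i in seq_along(laser$onsets)) {
    out <- out | (t >= laser$onsets[i] & t < laser$onsets[i] + laser$duration_s[i])
  }
  out
}

#' Downsample a hypnogram to a coarser epoch grid
#'
#' Used for transition-probability analyses (2.5 s to 10 s). Each coarse epoch
#' takes the majority state of its sub-epochs, ignoring `U`; ties are broken
#' with priority R > N > W so that rare-state transitions are preserved.
#'
#' @param h A `hypnogram`.
#' @param epoch_s Target epoch length, a multiple of `h$epoch_s`. Default 10.
#' @return A `hypnogram` on the coarser grid (trailing partial epoch dropped).
#' @export
downsample_hypnogram <- function(h, epoch_s = 10) {
  k <- epoch_s / h$epoch_s
  if (abs(k - round(k)) > 1e-9) stop("epoch_s must be a multiple of h$epoch_s")
  k <- round(k)
  n <- floor(length(h$states) / k)
  if (n < 1) stop("hypnogram shorter than one target epoch")
  prio <- c(R = 3, N = 2, W = 1, U = 0)
  out <- vapply(seq_len(n), function(i) {
    sub <- h$states[((i - 1) * k + 1):(i * k)]
    sub <- sub[sub != "U"]
    if (length(sub) == 0) return("U")
    tab <- table(sub)
    cand <- names(tab)[tab == max(tab)]
    cand[which.max(prio[cand])]
  }, character(1))
  hypnogram(out, epoch_s = epoch_s, t0 = h$t0)
}
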