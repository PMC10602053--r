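#' Construct a multichannel signal recording
#'
#' Container for sampled EEG/EMG channels in microvolts at a common sampling
#' rate. Sample `i` (1-based) maps to time `(i - 1) / fs` seconds.
#'
#' @param channels Named list of numeric vectors (equal lengths), e.g.
#'   `EEG_frontal`, `EEG_parietal`, `EMG`.
#' @param fs Sampling rate in Hz.
#' @return An object of class `signal_recording`.
#' @export
signal_recording <- function(channels, fs) {
  if (is.null(names(channels)) || any(!nzchar(names(channels))))
    stop("all channels must be named")
  lens <- vapply(channels, length, integer(1))
  if (length(unique(lens)) != 1)
    stop("all channels must have the same length (got ",
         paste(lens, collapse = ", "), ")")
  if (!is.numeric(fs) || fs <= 0) stop("fs must be a positive number")
  structure(list(channels = lapply(channels, as.numeric), fs = fs),
            class = "signal_recording")
}

#' @export
print.signal_recording <- function(x, ...) {
  n <- length(x$channels[[1]])
  cat(sprintf("signal_recording: %d channels x %d samples @ %g Hz (%.1f s)\n",
              length(x$channels), n, x$fs, n / x$fs))
  cat("  channels:", paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}

#' Number of samples per channel
#' @param rec A `signal_recording`.
#' @export
n_samples <- function(rec) length(rec$channels[[1]])

#' Fetch one channel, matching case-insensitively by substring
#'
#' EDF label dialects vary, so `"EMG"` matches e.g. `"EMG1"` or `"emg_nuchal"`.
#' An exact (case-insensitive) match wins over a substring match.
#'
#' @param rec A `signal_recording`.
#' @param name Channel name or substring.
#' @return Numeric vector of samples (microvolts).
#' @export
get_channel <- function(rec, name) {
  nm <- names(rec$channels)
  hit <- which(tolower(nm) == tolower(name))
  if (length(hit) == 0) hit <- grep(tolower(name), tolower(nm), fixed = TRUE)
  if (length(hit) == 0)
    stop("channel not found: ", name, " (have: ", paste(nm, collapse = ", "), ")")
  rec$channels[[hit[1]]]
}

#' Extract the samples of a channel within a time interval
#' @param rec A `signal_recording`.
#' @param name Channel name.
#' @param start_s,end_s Interval bounds in seconds (half-open `[start, end)`).
#' @export
channel_segment <- function(rec, name, start_s, end_s) {
  x <- get_channel(rec, name)
  i0 <- max(1L, floor(start_s * rec$fs) + 1L)
  i1 <- min(length(x), ceiling(end_s * rec$fs))
  x[i0:i1]
}

#' Read a recording from CSV or EDF
#'
#' The CSV dialect requires a header row naming the channels; the sampling
#' rate comes from a column named `fs` (constant), from a sidecar file
#' `<path>.fs` containing a single number, or from the `fs` argument.
#'
#' @param path File path.
#' @param format `"csv"` or `"edf"`; guessed from the extension by default.
#' @param channels Optional character vector of required channel names; an
#'   error naming the missing channel is raised if one is absent.
#' @param fs Sampling rate override for CSV input.
#' @return A `signal_recording` with channels in microvolts.
#' @export
read_recording <- function(path, format = c("auto", "csv", "edf"),
                           channels = NULL, fs = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  }
  rec <- if (format == "edf") read_edf(path) else read_recording_csv(path, fs)
  if (!is.null(channels)) {
    for (ch in channels) get_channel(rec, ch)  # errors name the channel
  }
  rec
}

read_recording_csv <- function(path, fs = NULL) {
  d <- read.csv(path, check.names = FALSE)
  if (is.null(fs)) {
    if ("fs" %in% names(d)) {
      fs <- d$fs[1]
      d$fs <- NULL
    } else if (file.exists(paste0(path, ".fs"))) {
      fs <- as.numeric(readLines(paste0(path, ".fs"))[1])
    } else {
      stop("sampling rate not found: provide an 'fs' column, a '", path,
           ".fs' sidecar, or the fs argument")
    }
  }
  signal_recording(as.list(d), fs = fs)
}

#' Write a recording as CSV (with an fs column)
#' @param rec A `signal_recording`.
#' @param path Output path.
#' @export
write_recording_csv <- function(rec, path) {
  d <- as.data.frame(rec$channels, check.names = FALSE)
  d$fs <- rec$fs
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}
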