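# Minimal EDF (European Data Format) reader/writer for continuous multichannel
# recordings. Covers the plain EDF layout used by polysomnography amplifiers:
# 256-byte fixed header, 256 bytes per signal header, then data records of
# 16-bit little-endian integers with per-signal physical/digital scaling.
# EDF+ annotation channels are not handled.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

edf_num <- function(x, width) {
  s <- formatC(x, format = "g", digits = 8)
  if (nchar(s) > width) s <- substr(formatC(x, format = "f", digits = width), 1, width)
  edf_pad(s, width)
}

#' Write a recording to an EDF file
#'
#' Samples are quantized to 16 bits over a symmetric physical range covering
#' each channel (so the round-trip error is at most range/65535).
#'
#' @param rec A `signal_recording`.
#' @param path Output path.
#' @param record_s Data-record duration in seconds (default 1). `fs * record_s`
#'   must be an integer; the trailing partial record is zero-padded on write
#'   and trimmed on read via the sample count stored in the header.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, record_s = 1) {
  ns <- length(rec$channels)
  spr <- rec$fs * record_s
  if (abs(spr - round(spr)) > 1e-9) stop("fs * record_s must be an integer")
  spr <- as.integer(round(spr))
  n <- n_samples(rec)
  n_rec <- ceiling(n / spr)
  con <- file(path, "wb")
  on.exit(close(con))

  phys_max <- vapply(rec$channels, function(x) max(1e-6, max(abs(x))), numeric(1))
  dig_max <- 32767

  hdr <- paste0(
    edf_pad("0", 8), edf_pad("X X X X", 80), edf_pad("Startdate X X X X", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (1 + ns), 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_num(record_s, 8), edf_pad(ns, 4))
  writeChar(hdr, con, eos = NULL)

  field <- function(vals, width) {
    writeChar(paste0(vapply(vals, edf_pad, character(1), width = width),
                     collapse = ""), con, eos = NULL)
  }
  field(names(rec$channels), 16)
  field(rep("", ns), 80)                       # transducer
  field(rep("uV", ns), 8)                      # physical dimension
  field(vapply(-phys_max, edf_num, character(1), width = 8), 8)
  field(vapply(phys_max, edf_num, character(1), width = 8), 8)
  field(rep(-dig_max - 1, ns), 8)
  field(rep(dig_max, ns), 8)
  field(rep("", ns), 80)                       # prefiltering
  field(rep(spr, ns), 8)
  field(rep("", ns), 32)                       # reserved

  # digital conversion: dig = round((phys - pmin) / (pmax - pmin) * (dmax - dmin) + dmin)
  for (r in seq_len(n_rec)) {
    i0 <- (r - 1) * spr + 1
    for (j in seq_len(ns)) {
      x <- rec$channels[[j]][i0:min(n, i0 + spr - 1)]
      if (length(x) < spr) x <- c(x, rep(0, spr - length(x)))
      pm <- phys_max[j]
      dig <- round((x + pm) / (2 * pm) * (2 * dig_max + 1) - dig_max - 1)
      dig <- pmin(pmax(dig, -dig_max - 1), dig_max)
      writeBin(as.integer(dig), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file into a signal_recording
#'
#' @param path EDF file path.
#' @param n_keep Optional number of samples to keep per channel (to trim the
#'   zero-padding of a final partial record). Defaults to all samples.
#' @return A `signal_recording` (channels in the file's physical units,
#'   expected to be microvolts).
#' @export
read_edf <- function(path, n_keep = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(k) trimws(readChar(con, k, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                   # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  record_s <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  rdv <- function(k) vapply(seq_len(ns), function(i) rd(k), character(1))
  labels <- rdv(16); rdv(80); rdv(8)
  pmin <- as.numeric(rdv(8)); pmax <- as.numeric(rdv(8))
  dmin <- as.numeric(rdv(8)); dmax <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8))
  rdv(32)
  if (length(unique(spr)) != 1)
    stop("EDF: differing samples/record across channels not supported")
  out <- lapply(seq_len(ns), function(j) numeric(n_rec * spr[j]))
  for (r in seq_len(n_rec)) {
    for (j in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[j], size = 2, endian = "little")
      phys <- (dig - dmin[j]) / (dmax[j] - dmin[j]) * (pmax[j] - pmin[j]) + pmin[j]
      out[[j]][((r - 1) * spr[j] + 1):(r * spr[j])] <- phys
    }
  }
  if (!is.null(n_keep)) out <- lapply(out, function(x) x[seq_len(n_keep)])
  names(out) <- labels
  signal_recording(out, fs = spr[1] / record_s)
}
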