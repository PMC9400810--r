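#' Minimal European Data Format (EDF) I/O
#'
#' Reads and writes plain EDF (16-bit, one-second data records). This covers
#' exactly what the pipeline needs — continuous multichannel recordings at a
#' single sampling rate — and is deterministic: fixed header date/time fields
#' so identical inputs produce byte-identical files.
#'
#' @name edf
NULL

.edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width, flag = " ")
}

#' Write a recording to an EDF file
#'
#' Physical scaling per channel spans the observed range (symmetric, with a
#' small margin) mapped onto the full 16-bit digital range, so quantization
#' error is at most range/65534 per sample.
#'
#' @param rec a `recording`; duration must be a whole number of seconds
#' @param path output path
#' @param patient_id,recording_id free-text EDF header fields
#' @return `path`, invisibly
#' @export
write_edf <- function(rec, path, patient_id = "X", recording_id = "synthetic") {
  ns <- nrow(rec$samples)
  nsamp <- ncol(rec$samples)
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) stop("EDF writer requires integer fs")
  fs <- as.integer(round(fs))
  n_rec <- nsamp %/% fs
  if (n_rec * fs != nsamp)
    stop("EDF writer requires a whole number of 1-s records")
  phys_max <- apply(abs(rec$samples), 1, max)
  phys_max <- ifelse(phys_max > 0, phys_max * 1.001, 1)
  phys_min <- -phys_max
  dig_max <- 32767L; dig_min <- -32767L
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edf_pad("0", 8), .edf_pad(patient_id, 80), .edf_pad(recording_id, 80),
    .edf_pad("01.01.00", 8), .edf_pad("00.00.00", 8),
    .edf_pad(256 * (1 + ns), 8), .edf_pad("", 44),
    .edf_pad(n_rec, 8), .edf_pad("1", 8), .edf_pad(ns, 4))
  field <- function(vals, width)
    paste(vapply(vals, .edf_pad, "", width = width), collapse = "")
  hdr <- paste0(hdr,
    field(rec$labels, 16), field(rep("", ns), 80), field(rec$units, 8),
    field(formatC(phys_min, format = "g", digits = 7), 8),
    field(formatC(phys_max, format = "g", digits = 7), 8),
    field(rep(dig_min, ns), 8), field(rep(dig_max, ns), 8),
    field(rep("", ns), 80), field(rep(fs, ns), 8), field(rep("", ns), 32))
  writeChar(hdr, con, eos = NULL)
  # re-read the printed physical range so write/read quantization agrees
  pmin_r <- as.numeric(formatC(phys_min, format = "g", digits = 7))
  pmax_r <- as.numeric(formatC(phys_max, format = "g", digits = 7))
  gain <- (dig_max - dig_min) / (pmax_r - pmin_r)
  dig <- matrix(0L, ns, nsamp)
  for (j in seq_len(ns)) {
    d <- round((rec$samples[j, ] - pmin_r[j]) * gain[j]) + dig_min
    dig[j, ] <- as.integer(pmin(pmax(d, dig_min), dig_max))
  }
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * fs + 1):(r * fs)
    writeBin(as.integer(t(dig[, cols, drop = FALSE])), con, size = 2,
             endian = "little")
  }
  invisible(path)
}

#' Read an EDF file into a recording
#'
#' @param path EDF path
#' @return a `recording` in physical units
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) {
    raw <- readChar(con, w, useBytes = TRUE)
    trimws(raw)
  }
  rd(8)                       # version
  rd(80); rd(80); rd(8); rd(8)
  rd(8)                       # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  rdv <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- rdv(16); rdv(80)
  units <- rdv(8)
  phys_min <- as.numeric(rdv(8)); phys_max <- as.numeric(rdv(8))
  dig_min <- as.numeric(rdv(8)); dig_max <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8))   # samples per record, per signal
  rdv(32)
  if (length(unique(spr)) != 1L)
    stop("mixed per-signal sampling rates are not supported")
  fs <- spr[1] / rec_dur
  out <- matrix(0, ns, n_rec * spr[1])
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_rec)) {
    blk <- readBin(con, integer(), n = ns * spr[1], size = 2,
                   endian = "little")
    m <- matrix(blk, nrow = spr[1], ncol = ns)
    cols <- ((r - 1) * spr[1] + 1):(r * spr[1])
    out[, cols] <- t(m) * gain + (phys_min - dig_min * gain)
  }
  recording(out, fs, labels, units)
}
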