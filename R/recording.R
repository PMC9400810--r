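#' Multichannel biosignal recording
#'
#' The common carrier for EEG and ECG: a channels-by-time numeric matrix with
#' a sampling rate, unique channel labels and per-channel physical units
#' (conventionally uV for EEG channels, mV for ECG).
#'
#' @param samples numeric matrix, channels in rows, samples in columns
#' @param fs sampling rate in Hz
#' @param labels character vector of unique channel names
#' @param units character vector of per-channel units (recycled if length 1)
#' @param start_time recording start offset in seconds
#' @return an object of class `recording`
#' @export
recording <- function(samples, fs, labels, units = "uV", start_time = 0) {
  samples <- as.matrix(samples)
  dimnames(samples) <- NULL
  if (length(labels) != nrow(samples))
    stop("labels must match the number of channels")
  if (anyDuplicated(labels)) stop("channel labels must be unique")
  if (!is.numeric(fs) || fs <= 0) stop("fs must be a positive number")
  units <- rep_len(units, nrow(samples))
  structure(list(samples = samples, fs = fs, labels = as.character(labels),
                 units = units, start_time = start_time),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$samples), ncol(x$samples), x$fs,
              ncol(x$samples) / x$fs))
  cat("  channels:", paste(x$labels, collapse = " "), "\n")
  invisible(x)
}

#' Number of samples per channel
#' @param rec a `recording`
#' @return integer sample count
#' @export
n_samples <- function(rec) ncol(rec$samples)

#' Extract channels by label
#'
#' @param rec a `recording`
#' @param labels channel names to keep (case-insensitive, 10/20 synonyms
#'   T3/T4/T5/T6 = T7/T8/P7/P8 resolved)
#' @return a `recording` with the requested channels, in the requested order
#' @export
pick_channels <- function(rec, labels) {
  idx <- match_channel(labels, rec$labels)
  recording(rec$samples[idx, , drop = FALSE], rec$fs, rec$labels[idx],
            rec$units[idx], rec$start_time)
}

# 10/20 synonym table: older temporal nomenclature vs modified system
.ten20_synonyms <- c(T3 = "T7", T4 = "T8", T5 = "P7", T6 = "P8",
                     T7 = "T3", T8 = "T4", P7 = "T5", P8 = "T6")

#' Resolve channel labels against a montage
#'
#' Case-insensitive matching with the T3/T7-style synonym table. Errors on
#' unresolvable labels rather than silently dropping them.
#'
#' @param wanted labels to look up
#' @param have montage labels
#' @return integer indices into `have`
#' @export
match_channel <- function(wanted, have) {
  hu <- toupper(have)
  idx <- match(toupper(wanted), hu)
  for (k in which(is.na(idx))) {
    syn <- .ten20_synonyms[toupper(wanted[k])]
    if (!is.na(syn)) idx[k] <- match(syn, hu)
  }
  if (anyNA(idx))
    stop("unresolvable channel label(s): ",
         paste(wanted[is.na(idx)], collapse = ", "))
  idx
}

#' The 19-channel 10/20 EEG montage used throughout
#' @return character vector of channel names
#' @export
montage_1020 <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "T3", "C3", "Cz", "C4", "T4",
    "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
}

#' Read a recording from a numeric CSV (one column per channel, header row)
#'
#' @param path CSV path
#' @param fs sampling rate in Hz (CSV carries no rate)
#' @param units per-channel units
#' @return a `recording`
#' @export
read_recording_csv <- function(path, fs, units = "uV") {
  d <- utils::read.csv(path, check.names = FALSE)
  recording(t(as.matrix(d)), fs, colnames(d), units)
}

#' Write a recording as CSV (one column per channel, header row)
#'
#' @param rec a `recording`
#' @param path output path
#' @export
write_recording_csv <- function(rec, path) {
  d <- as.data.frame(t(rec$samples))
  colnames(d) <- rec$labels
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
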