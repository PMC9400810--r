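#' EEG preprocessing and band/ROI power mapping
#'
#' Produces the subject x band x (ROI, hemisphere) mean-power table in dB
#' that serves as the regression predictors F, C, P, T, O, plus the
#' grand-average spectrum and the alpha peak frequency.
#'
#' @name eeg_power
NULL

#' The canonical band scheme (closed-open ranges in Hz)
#'
#' delta [1,4), theta [4,8), alpha1 [8,10), alpha2 [10,13), beta [13,31).
#'
#' @return data.frame with columns band, lo, hi
#' @export
eeg_bands <- function() {
  data.frame(band = c("delta", "theta", "alpha1", "alpha2", "beta"),
             lo = c(1, 4, 8, 10, 13),
             hi = c(4, 8, 10, 13, 31))
}

#' The (ROI, hemisphere) -> channel-set map
#'
#' Frontal: Fp1/F3/F7 (L), Fp2/F4/F8 (R); Central: C3 (L), C4 (R);
#' Temporal: T3/T5 (L), T4/T6 (R); Parietal: P3/P4; Occipital: O1/O2.
#' Midline channels (Fz, Cz, Pz) belong to no ROI.
#'
#' @return data.frame with columns roi, hemisphere and list-column channels
#' @export
eeg_rois <- function() {
  r <- data.frame(roi = c("F", "F", "C", "C", "T", "T", "P", "P", "O", "O"),
                  hemisphere = rep(c("L", "R"), 5))
  r$channels <- list(c("Fp1", "F3", "F7"), c("Fp2", "F4", "F8"),
                     "C3", "C4", c("T3", "T5"), c("T4", "T6"),
                     "P3", "P4", "O1", "O2")
  r
}

#' Preprocess an EEG recording
#'
#' Zero-phase 4th-order Butterworth band-pass 0.5-100 Hz, zero-phase 50 Hz
#' notch (Q = 30), then re-referencing: to the mean of the two mastoids when
#' `A1`/`A2` (or `M1`/`M2`) are present, otherwise to the common average with
#' a logged downgrade. One-second windows exceeding `reject_uV` on any
#' channel are flagged in the `bad_seconds` attribute (they are not removed;
#' heartbeat epoching applies its own rejection).
#'
#' @param eeg a `recording` with at least the 19 named 10/20 channels
#' @param bp_hz band-pass edges in Hz
#' @param notch_hz mains frequency (set `NULL` to disable)
#' @param notch_q notch quality factor
#' @param reject_uV amplitude flag threshold in uV
#' @return preprocessed `recording` restricted to the 19 montage channels,
#'   with attributes `reference` ("linked_mastoids" or "common_average") and
#'   `bad_seconds`
#' @export
preprocess_eeg <- function(eeg, bp_hz = c(0.5, 100), notch_hz = 50,
                           notch_q = 30, reject_uV = 150) {
  if (anyNA(eeg$samples)) stop("NaN/NA samples in input")
  idx <- match_channel(montage_1020(), eeg$labels)  # errors if missing
  if (abs(eeg$fs - 256) > 1e-6)
    warning("nominal sampling rate is 256 Hz; got ", eeg$fs)
  mast <- intersect(c("A1", "A2", "M1", "M2"), toupper(eeg$labels))
  bp <- butter_filter(4, bp_hz, eeg$fs, "pass")
  nf <- if (!is.null(notch_hz)) notch_filter(notch_hz, eeg$fs, notch_q)
  work_labels <- unique(c(eeg$labels[idx],
                          eeg$labels[toupper(eeg$labels) %in% mast]))
  widx <- match(work_labels, eeg$labels)
  M <- t(eeg$samples[widx, , drop = FALSE])   # samples x channels
  # 4 s of reflection padding: the slowest pole (0.5 Hz edge) decays e-fold
  # every ~0.3 s, so start-up transients are < 1e-5 of signal scale
  M <- filtfilt(bp$b, bp$a, M, padlen = min(nrow(M) - 1L,
                                            as.integer(4 * eeg$fs)))
  if (!is.null(nf)) M <- filtfilt(nf$b, nf$a, M)
  filtered <- t(M)
  if (length(mast) >= 2) {
    mrows <- which(toupper(work_labels) %in% mast)[1:2]
    ref <- colMeans(filtered[mrows, , drop = FALSE])
    reference <- "linked_mastoids"
  } else {
    mont_rows <- match(eeg$labels[idx], work_labels)
    ref <- colMeans(filtered[mont_rows, , drop = FALSE])
    reference <- "common_average"
    message("mastoid channels absent: re-referencing to common average")
  }
  mont_rows <- match(eeg$labels[idx], work_labels)
  refd <- sweep(filtered[mont_rows, , drop = FALSE], 2, ref)
  out <- recording(refd, eeg$fs, montage_1020(), units = "uV",
                   start_time = eeg$start_time)
  nsec <- floor(ncol(refd) / eeg$fs)
  bad <- integer(0)
  if (nsec >= 1) {
    for (s in seq_len(nsec)) {
      cols <- ((s - 1) * eeg$fs + 1):(s * eeg$fs)
      if (max(abs(refd[, cols])) > reject_uV) bad <- c(bad, s)
    }
  }
  attr(out, "reference") <- reference
  attr(out, "bad_seconds") <- bad
  out
}

#' Per-channel Welch PSDs of a recording
#'
#' 4-s Hamming segments, 0% overlap (the band-power defaults).
#'
#' @param rec a `recording`
#' @param nperseg,overlap Welch parameters
#' @return named list of `psd` objects, one per channel
#' @export
channel_psds <- function(rec, nperseg = round(4 * rec$fs), overlap = 0) {
  out <- lapply(seq_len(nrow(rec$samples)), function(i)
    welch_psd(rec$samples[i, ], rec$fs, nperseg = nperseg, overlap = overlap))
  names(out) <- rec$labels
  out
}

#' Band x (ROI, hemisphere) mean power table
#'
#' Per channel, the mean PSD density over each band's bins is converted to
#' dB (10 log10, relative to 1 uV^2/Hz); the ROI value is the arithmetic
#' mean of its member channels' dB values (configurable to linear-domain
#' averaging before the dB transform).
#'
#' @param psds named list of per-channel `psd` objects
#' @param bands band scheme (data.frame as from [eeg_bands()])
#' @param rois ROI map (data.frame as from [eeg_rois()])
#' @param average "db" (average the dB values, default) or "linear"
#'   (average linear densities, then convert)
#' @return data.frame: band, roi, hemisphere, power_db, with the per-channel
#'   dB matrix attached as attribute `channel_db`
#' @export
band_roi_power <- function(psds, bands = eeg_bands(), rois = eeg_rois(),
                           average = c("db", "linear")) {
  average <- match.arg(average)
  ch_lin <- sapply(psds, function(p)
    vapply(seq_len(nrow(bands)), function(bi)
      band_mean_density(p, bands$lo[bi], bands$hi[bi]), numeric(1)))
  rownames(ch_lin) <- bands$band
  if (any(ch_lin <= 0))
    stop("non-positive linear band power; cannot take dB")
  ch_db <- 10 * log10(ch_lin)
  rows <- lapply(seq_len(nrow(rois)), function(ri) {
    members <- match_channel(rois$channels[[ri]], colnames(ch_db))
    val <- if (average == "db")
      rowMeans(ch_db[, members, drop = FALSE])
    else
      10 * log10(rowMeans(ch_lin[, members, drop = FALSE]))
    data.frame(band = bands$band, roi = rois$roi[ri],
               hemisphere = rois$hemisphere[ri], power_db = val)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "channel_db") <- ch_db
  out
}

#' Alpha peak frequency of a posterior mean spectrum
#'
#' Locates the maximum of the PSD within the search range and refines it by
#' local quadratic interpolation. A "no peak" flag is returned when the
#' maximum sits on a range boundary or does not stand out from the range's
#' median density by at least `min_prominence_db` (a flat/white spectrum has
#' no meaningful alpha peak).
#'
#' @param psd a `psd` object (typically the mean over occipital + parietal
#'   channels)
#' @param range search range in Hz
#' @param min_prominence_db required peak height above the in-range median
#' @return list: `apf_hz` (NA when no peak), `peak_found`
#' @export
alpha_peak_frequency <- function(psd, range = c(7, 13),
                                 min_prominence_db = 2) {
  sel <- which(psd$freq >= range[1] & psd$freq <= range[2])
  if (length(sel) < 3) stop("PSD grid does not cover the alpha search range")
  p <- psd$power[sel]
  i <- which.max(p)
  prom_db <- 10 * log10(p[i] / stats::median(p))
  if (i == 1L || i == length(sel) || prom_db < min_prominence_db)
    return(list(apf_hz = NA_real_, peak_found = FALSE))
  df <- psd$freq[2] - psd$freq[1]
  y1 <- p[i - 1]; y2 <- p[i]; y3 <- p[i + 1]
  delta <- 0.5 * (y1 - y3) / (y1 - 2 * y2 + y3)
  list(apf_hz = psd$freq[sel[i]] + delta * df, peak_found = TRUE)
}

#' Mean PSD over a channel subset
#'
#' @param psds named list of per-channel `psd` objects
#' @param channels channel names to average (default: occipital + parietal)
#' @return a `psd` object
#' @export
mean_psd <- function(psds, channels = c("O1", "O2", "P3", "P4", "Pz")) {
  idx <- match_channel(channels, names(psds))
  base <- psds[[idx[1]]]
  pw <- rowMeans(sapply(idx, function(i) psds[[i]]$power))
  structure(list(freq = base$freq, power = pw, fs = base$fs,
                 nperseg = base$nperseg, overlap = base$overlap,
                 n_segments = base$n_segments), class = "psd")
}
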