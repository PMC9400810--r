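#' Welch averaged-periodogram power spectral density
#'
#' Hamming-windowed averaged periodogram with density scaling (one-sided).
#' EEG band power uses 4-s segments with 0% overlap; the HRV tachogram
#' spectrum uses 256-point segments with 50% overlap.
#'
#' @param x numeric signal
#' @param fs sampling rate in Hz
#' @param nperseg segment length in samples (default `4 * fs`)
#' @param overlap fractional overlap between segments in [0, 1)
#' @param detrend_segments subtract each segment's mean before windowing
#' @return object of class `psd`: list with `freq` (Hz) and `power`
#'   (signal-units squared per Hz)
#' @export
welch_psd <- function(x, fs, nperseg = round(4 * fs), overlap = 0,
                      detrend_segments = TRUE) {
  n <- length(x)
  nperseg <- as.integer(nperseg)
  if (nperseg > n) stop("segment longer than data (", nperseg, " > ", n, ")")
  step <- max(1L, as.integer(round(nperseg * (1 - overlap))))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- hamming_window(nperseg)
  scale <- 1 / (fs * sum(w^2))
  nfreq <- nperseg %/% 2L + 1L
  segs <- vapply(starts, function(s) x[s:(s + nperseg - 1L)],
                 numeric(nperseg))
  if (detrend_segments)
    segs <- sweep(segs, 2, colMeans(segs))
  X <- stats::mvfft(segs * w)[seq_len(nfreq), , drop = FALSE]
  p <- rowMeans(Mod(X)^2) * scale
  # one-sided: double everything except DC and (for even nperseg) Nyquist
  dbl <- rep(2, nfreq)
  dbl[1] <- 1
  if (nperseg %% 2L == 0L) dbl[nfreq] <- 1
  p <- p * dbl
  structure(list(freq = (seq_len(nfreq) - 1) * fs / nperseg, power = p,
                 fs = fs, nperseg = nperseg, overlap = overlap,
                 n_segments = length(starts)),
            class = "psd")
}

#' @rdname welch_psd
#' @param n window length
#' @export
hamming_window <- function(n) {
  0.54 - 0.46 * cos(2 * pi * seq(0, n - 1) / (n - 1))
}

#' Integrate a PSD over a frequency band
#'
#' Rectangular (bin-width) integration over bins whose centre falls in
#' `[lo, hi)`.
#'
#' @param psd a `psd` object
#' @param lo,hi band edges in Hz (closed-open)
#' @return integrated power in signal-units squared
#' @export
band_integral <- function(psd, lo, hi) {
  df <- psd$freq[2] - psd$freq[1]
  sel <- psd$freq >= lo & psd$freq < hi
  if (!any(sel)) stop("no PSD bins in band [", lo, ", ", hi, ")")
  sum(psd$power[sel]) * df
}

#' Mean PSD density over a frequency band
#'
#' @inheritParams band_integral
#' @return mean density in signal-units squared per Hz
#' @export
band_mean_density <- function(psd, lo, hi) {
  sel <- psd$freq >= lo & psd$freq < hi
  if (!any(sel)) stop("no PSD bins in band [", lo, ", ", hi, ")")
  mean(psd$power[sel])
}
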