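#' Heart rate variability metrics
#'
#' The four parameters used throughout: SDNN, RMSSD, SD1 and absolute HF
#' power (0.15-0.40 Hz). SD1 is computed from the Poincare rotated-axis
#' construction (RMS dispersion about the line of identity) and equals
#' RMSSD/sqrt(2) algebraically; both routes are computed and cross-checked.
#'
#' @name hrv
NULL

.nn_intervals <- function(nn) {
  if (inherits(nn, "nn_series")) nn$intervals_ms else as.numeric(nn)
}

#' Time-domain HRV: SDNN, RMSSD, SD1
#'
#' SDNN is the sample standard deviation (denominator N-1) of the NN
#' intervals. RMSSD is the root mean square of successive differences. SD1
#' is the RMS of the rotated Poincare coordinate (NN_{k+1} - NN_k)/sqrt(2),
#' i.e. dispersion about the identity line.
#'
#' @param nn an `nn_series` or numeric vector of NN intervals in ms
#' @return list: `sdnn_ms`, `rmssd_ms`, `sd1_ms`, `n_intervals`
#' @export
compute_time_domain <- function(nn) {
  iv <- .nn_intervals(nn)
  if (length(iv) < 3) stop("need at least 3 NN intervals")
  d <- diff(iv)
  rmssd <- sqrt(mean(d^2))
  sd1 <- sqrt(mean(((iv[-1] - iv[-length(iv)]) / sqrt(2))^2))
  if (rmssd > 0 && abs(sd1 - rmssd / sqrt(2)) > 1e-9 * rmssd)
    stop("internal inconsistency: SD1 != RMSSD/sqrt(2)")
  list(sdnn_ms = stats::sd(iv), rmssd_ms = rmssd, sd1_ms = sd1,
       n_intervals = length(iv))
}

#' Absolute high-frequency (0.15-0.40 Hz) power of the NN tachogram
#'
#' The irregularly sampled tachogram is cubic-spline resampled onto a
#' uniform 4 Hz grid, linearly detrended, and its Welch periodogram (Hamming
#' window, 256-point segments — shortened to the record when the record is
#' shorter — 50% overlap) integrated over the HF band.
#'
#' @param nn an `nn_series`, or a numeric vector of NN intervals in ms (then
#'   `times_s` must be given)
#' @param times_s time of each interval's terminating beat, seconds
#' @param resample_hz tachogram resampling rate
#' @param band HF band edges in Hz
#' @return HF power in ms^2
#' @export
compute_hf_power <- function(nn, times_s = NULL, resample_hz = 4,
                             band = c(0.15, 0.40)) {
  if (inherits(nn, "nn_series")) {
    iv <- nn$intervals_ms; tv <- nn$times_s
  } else {
    iv <- as.numeric(nn); tv <- times_s
  }
  if (!length(iv)) stop("empty NN series")
  if (is.null(tv) || length(tv) != length(iv))
    stop("interval times are required for spectral analysis")
  span <- tv[length(tv)] - tv[1]
  if (span < 60) stop("recording span too short for HF power (need >= 60 s)")
  grid <- seq(tv[1], tv[length(tv)], by = 1 / resample_hz)
  y <- stats::spline(tv, iv, xout = grid, method = "fmm")$y
  # linear detrend
  fit <- stats::lm.fit(cbind(1, grid), y)
  y <- fit$residuals
  nperseg <- min(256L, length(y))
  psd <- welch_psd(y, resample_hz, nperseg = nperseg, overlap = 0.5,
                   detrend_segments = TRUE)
  band_integral(psd, band[1], band[2])
}

#' Per-subject HRV summary
#'
#' @param nn an `nn_series`
#' @param compute_hf set `FALSE` to skip spectral analysis (short records)
#' @return object of class `hrv_summary`: `sdnn_ms`, `rmssd_ms`, `sd1_ms`,
#'   `hf_ms2` (NA when skipped), `n_intervals`, plus a `conventions`
#'   metadata list recording the computational choices
#' @export
hrv_summary <- function(nn, compute_hf = TRUE) {
  td <- compute_time_domain(nn)
  hf <- if (compute_hf) compute_hf_power(nn) else NA_real_
  structure(c(td["sdnn_ms"], td["rmssd_ms"], td["sd1_ms"],
              list(hf_ms2 = hf, n_intervals = td$n_intervals,
                   conventions = list(
                     sdnn_denominator = "N-1",
                     sd1 = "Poincare rotated axis == RMSSD/sqrt(2)",
                     hf = "spline 4 Hz, linear detrend, Welch Hamming 256 pt 50% overlap, [0.15,0.40) Hz",
                     window = "full usable NN record"))),
            class = "hrv_summary")
}

#' @export
print.hrv_summary <- function(x, ...) {
  cat(sprintf(
    "<hrv_summary> SDNN %.1f ms, RMSSD %.1f ms, SD1 %.1f ms, HF %s ms^2 (n=%d)\n",
    x$sdnn_ms, x$rmssd_ms, x$sd1_ms,
    if (is.na(x$hf_ms2)) "NA" else sprintf("%.0f", x$hf_ms2),
    x$n_intervals))
  invisible(x)
}
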