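#' QRS detection and NN interval derivation
#'
#' A Pan-Tompkins-style detector: band-pass 5-15 Hz, five-point derivative,
#' squaring, 150 ms moving-window integration, adaptive dual-threshold peak
#' picking with a 200 ms refractory period and search-back. Squaring makes
#' the chain polarity-invariant (a bipolar limb lead may be inverted), and
#' every decision threshold is derived from the data, so detections are
#' invariant to positive rescaling of the trace.
#'
#' @name ecg_rpeak
NULL

#' Detect R peaks in a single-channel ECG
#'
#' @param ecg a `recording`; the channel named "ECG" is used if present,
#'   otherwise the recording must have exactly one channel
#' @param refine_ms half-width of the window around each integrator peak in
#'   which the detection is refined to the raw-trace extremum (absolute
#'   deviation from the trace median, so polarity does not matter)
#' @return object of class `rpeak_train`: list with `peak_indices` (1-based
#'   sample indices, strictly increasing) and `fs`
#' @export
detect_r_peaks <- function(ecg, refine_ms = 50) {
  if (nrow(ecg$samples) > 1) {
    i <- which(toupper(ecg$labels) == "ECG")
    if (length(i) != 1) stop("give a single-channel recording or label one channel 'ECG'")
    x <- ecg$samples[i, ]
  } else x <- ecg$samples[1, ]
  fs <- ecg$fs
  if (fs < 100) stop("sampling rate too low for QRS detection (need >= 100 Hz)")
  if (length(x) < 10 * fs) stop("need at least 10 s of ECG")
  if (stats::sd(x) == 0) stop("no peaks: flat input")

  bp <- butter_filter(4, c(5, 15), fs, "pass")
  xf <- filtfilt(bp$b, bp$a, x)
  # five-point derivative, centered (no group delay to undo)
  dv <- as.numeric(stats::filter(xf, c(2, 1, 0, -1, -2) / 8, sides = 2))
  dv[is.na(dv)] <- 0
  sq <- dv^2
  w <- max(1L, round(0.15 * fs))
  mwi <- as.numeric(stats::filter(sq, rep(1 / w, w), sides = 2))
  mwi[is.na(mwi)] <- 0

  n <- length(mwi)
  cand <- which(mwi[2:(n - 1)] > mwi[1:(n - 2)] &
                mwi[2:(n - 1)] >= mwi[3:n]) + 1L
  cand <- cand[mwi[cand] > 0]
  if (!length(cand)) stop("no peaks detected")

  init <- seq_len(min(n, 2L * as.integer(fs)))
  spki <- 0.875 * max(mwi[init])
  npki <- 0.5 * mean(mwi[init])
  refr <- round(0.2 * fs)
  accepted <- integer(0)
  rr_buf <- numeric(0)
  last <- -Inf
  for (ci in seq_along(cand)) {
    i <- cand[ci]
    thr1 <- npki + 0.25 * (spki - npki)
    if (i - last < refr) next
    if (mwi[i] > thr1) {
      accepted <- c(accepted, i)
      if (length(accepted) > 1) {
        rr_buf <- c(rr_buf, i - last)
        if (length(rr_buf) > 8) rr_buf <- rr_buf[-1]
      }
      last <- i
      spki <- 0.125 * mwi[i] + 0.875 * spki
    } else {
      npki <- 0.125 * mwi[i] + 0.875 * npki
      # search-back: no beat for 1.66 x the running average RR
      if (length(rr_buf) >= 2 && i - last > 1.66 * mean(rr_buf)) {
        gap <- cand[cand > last + refr & cand < i]
        if (length(gap)) {
          g <- gap[which.max(mwi[gap])]
          if (mwi[g] > 0.5 * thr1) {
            accepted <- c(accepted, g)
            rr_buf <- c(rr_buf, g - last)
            if (length(rr_buf) > 8) rr_buf <- rr_buf[-1]
            last <- g
            spki <- 0.25 * mwi[g] + 0.75 * spki
          }
        }
      }
    }
  }
  if (!length(accepted)) stop("no peaks detected")

  # the integrator peak can sit tens of ms off the R wave; first snap to the
  # QRS-band energy maximum (T/P waves are suppressed at 5-15 Hz), then to
  # the raw-trace extremum
  half_bp <- round(0.15 * fs)
  snapped <- vapply(accepted, function(i) {
    lo <- max(1L, i - half_bp); hi <- min(length(x), i + half_bp)
    as.integer(lo + which.max(abs(xf[lo:hi])) - 1L)
  }, integer(1))
  half <- round(refine_ms / 1000 * fs)
  med <- stats::median(x)
  refined <- vapply(snapped, function(i) {
    lo <- max(1L, i - half); hi <- min(length(x), i + half)
    as.integer(lo + which.max(abs(x[lo:hi] - med)) - 1L)
  }, integer(1))
  refined <- sort(unique(refined))
  # enforce refractory after refinement, keeping the larger deflection
  keep <- rep(TRUE, length(refined))
  j <- 1L
  for (k in seq_along(refined)[-1]) {
    if (refined[k] - refined[j] < refr) {
      if (abs(x[refined[k]] - med) > abs(x[refined[j]] - med)) {
        keep[j] <- FALSE; j <- k
      } else keep[k] <- FALSE
    } else j <- k
  }
  structure(list(peak_indices = refined[keep], fs = fs),
            class = "rpeak_train")
}

#' @export
print.rpeak_train <- function(x, ...) {
  cat(sprintf("<rpeak_train> %d peaks @ %g Hz\n", length(x$peak_indices),
              x$fs))
  invisible(x)
}

#' Derive the normal-to-normal (NN) interval series from an R-peak train
#'
#' Successive peak-time differences in ms. Intervals outside (300, 2000) ms,
#' or deviating more than `max_dev` from the running median of the previous
#' (up to) five accepted intervals, are excluded and counted; gaps are not
#' interpolated.
#'
#' @param peaks an `rpeak_train`
#' @param max_dev maximum fractional deviation from the running median
#' @return object of class `nn_series`: `intervals_ms`, `times_s` (time of
#'   each interval's terminating beat), `n_rejected`
#' @export
to_nn_series <- function(peaks, max_dev = 0.20) {
  if (length(peaks$peak_indices) < 3) stop("need at least 3 peaks")
  iv <- diff(peaks$peak_indices) / peaks$fs * 1000
  tv <- peaks$peak_indices[-1] / peaks$fs
  keep_iv <- numeric(0); keep_tv <- numeric(0)
  n_rej <- 0L
  for (k in seq_along(iv)) {
    ok <- iv[k] > 300 && iv[k] < 2000
    if (ok && length(keep_iv)) {
      m <- stats::median(utils::tail(keep_iv, 5))
      ok <- abs(iv[k] - m) <= max_dev * m
    }
    if (ok) {
      keep_iv <- c(keep_iv, iv[k]); keep_tv <- c(keep_tv, tv[k])
    } else n_rej <- n_rej + 1L
  }
  if (length(keep_iv) < 2) stop("insufficient data: <2 surviving NN intervals")
  structure(list(intervals_ms = keep_iv, times_s = keep_tv,
                 n_rejected = n_rej),
            class = "nn_series")
}

#' @export
print.nn_series <- function(x, ...) {
  cat(sprintf("<nn_series> %d intervals (%d rejected), mean %.0f ms\n",
              length(x$intervals_ms), x$n_rejected, mean(x$intervals_ms)))
  invisible(x)
}

#' Write / read the two-column RR interchange CSV (time_s, rr_ms)
#'
#' @param nn an `nn_series`
#' @param path CSV path
#' @export
write_rr_csv <- function(nn, path) {
  utils::write.csv(data.frame(time_s = nn$times_s, rr_ms = nn$intervals_ms),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rr_csv
#' @export
read_rr_csv <- function(path) {
  d <- utils::read.csv(path)
  structure(list(intervals_ms = d$rr_ms, times_s = d$time_s,
                 n_rejected = 0L), class = "nn_series")
}
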