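#' Heartbeat-evoked potentials
#'
#' R-peak-locked EEG epoching, trial averaging, and detection of
#' channel-by-channel time windows with significant group differences inside
#' the 350-600 ms window of interest (chosen to sit past the cardiac-field
#' artifact).
#'
#' @name hep
NULL

#' Epoch EEG around R peaks
#'
#' The continuous EEG is zero-phase low-pass filtered at `lp_hz` first, then
#' cut into [-200, +600) ms epochs: sample offsets `round(-0.2 fs)` to
#' `round(0.6 fs) - 1` relative to each R peak, so the time axis contains 0
#' (the R peak). Epochs that would overlap a following R peak are retained
#' (unavoidable at RR < 800 ms) — a message reports how many. Trials with
#' any sample beyond `reject_uV` are dropped and counted.
#'
#' @param eeg a `recording` (uV)
#' @param peaks an `rpeak_train`
#' @param lp_hz low-pass edge in Hz
#' @param tmin,tmax epoch window in seconds relative to the R peak
#' @param reject_uV per-trial absolute amplitude rejection threshold
#' @param min_beats minimum number of usable beats
#' @return object of class `hep_epochs`: array `data` (channel x trial x
#'   time), `time_ms`, `fs`, `n_trials`, `rejected_trials`, `labels`
#' @export
epoch_heartbeats <- function(eeg, peaks, lp_hz = 15, tmin = -0.2, tmax = 0.6,
                             reject_uV = 100, min_beats = 30) {
  fs <- eeg$fs
  if (!isTRUE(all.equal(fs, peaks$fs))) stop("EEG and peak train fs differ")
  o1 <- round(tmin * fs)
  o2 <- round(tmax * fs) - 1L
  n <- n_samples(eeg)
  p <- peaks$peak_indices
  usable <- p + o1 >= 1L & p + o2 <= n
  if (any(!usable))
    message(sum(!usable), " peak(s) too close to the record edge dropped")
  p <- p[usable]
  if (length(p) < min_beats)
    stop("need at least ", min_beats, " usable beats, have ", length(p))
  n_overlap <- sum(diff(p) < round(0.8 * fs))
  if (n_overlap > 0)
    message(n_overlap, " epoch(s) overlap the next R peak (RR < 800 ms); retained")
  lp <- butter_filter(4, lp_hz, fs, "low")
  filt <- t(apply(eeg$samples, 1, function(v) filtfilt(lp$b, lp$a, v)))
  offs <- o1:o2
  nch <- nrow(filt)
  arr <- array(NA_real_, c(nch, length(p), length(offs)))
  for (k in seq_along(p)) arr[, k, ] <- filt[, p[k] + offs, drop = FALSE]
  bad <- apply(arr, 2, function(tr) any(abs(tr) > reject_uV))
  arr <- arr[, !bad, , drop = FALSE]
  if (dim(arr)[2] == 0L) stop("all trials rejected")
  structure(list(data = arr, time_ms = offs / fs * 1000, fs = fs,
                 n_trials = dim(arr)[2], rejected_trials = sum(bad),
                 labels = eeg$labels),
            class = "hep_epochs")
}

#' Average epochs into a per-subject HEP
#'
#' @param epochs a `hep_epochs`
#' @param baseline optional length-2 ms window whose per-trial mean is
#'   subtracted (default `NULL` = off; the pre-R interval carries cardiac
#'   field, so baselining is contentious for HEP)
#' @param max_trials optional cap: only the first `max_trials` accepted
#'   trials enter the average
#' @return object of class `hep_average`: matrix `waveforms` (channel x
#'   time, uV), `time_ms`, `n_trials_used`, `labels`, `baseline`
#' @export
average_hep <- function(epochs, baseline = NULL, max_trials = NULL) {
  arr <- epochs$data
  nt <- dim(arr)[2]
  if (nt < 1) stop("zero surviving trials")
  if (!is.null(max_trials) && max_trials < nt)
    arr <- arr[, seq_len(max_trials), , drop = FALSE]
  if (!is.null(baseline)) {
    bsel <- epochs$time_ms >= baseline[1] & epochs$time_ms <= baseline[2]
    if (!any(bsel)) stop("baseline window outside the epoch")
    bl <- apply(arr[, , bsel, drop = FALSE], c(1, 2), mean)
    arr <- sweep(arr, c(1, 2), bl)
  }
  wf <- apply(arr, c(1, 3), mean)
  structure(list(waveforms = wf, time_ms = epochs$time_ms,
                 n_trials_used = dim(arr)[2], labels = epochs$labels,
                 baseline = baseline),
            class = "hep_average")
}

#' Channel-wise group comparison of HEP amplitude
#'
#' The statistical unit is the per-subject average HEP. At every sample in
#' the window of interest, a two-group one-way ANOVA is run per channel;
#' sample-wise p-values are Bonferroni-corrected by the number of tested
#' samples per channel; corrected-significant samples are merged into
#' maximal contiguous windows, windows shorter than `min_win_ms` are
#' discarded, and each window reports the minimum corrected p inside it.
#'
#' @param heps_a,heps_b lists of `hep_average` objects (one per subject per
#'   group), on a common time axis and channel set
#' @param toi window of interest in ms
#' @param alpha significance level applied to corrected p-values
#' @param min_win_ms minimum reportable window length
#' @return data.frame: channel, t_start_ms, t_end_ms, p_corrected (empty
#'   when nothing is significant); per-channel/sample F and corrected p kept
#'   in attributes `F_matrix`, `p_matrix`, `time_ms`
#' @export
compare_groups_hep <- function(heps_a, heps_b, toi = c(350, 600),
                               alpha = 0.05, min_win_ms = 20) {
  if (length(heps_a) < 2 || length(heps_b) < 2)
    stop("need at least 2 subjects per group")
  t_ms <- heps_a[[1]]$time_ms
  labels <- heps_a[[1]]$labels
  for (h in c(heps_a, heps_b))
    if (!isTRUE(all.equal(h$time_ms, t_ms)))
      stop("subjects are not on a common time axis")
  sel <- which(t_ms >= toi[1] & t_ms <= toi[2])
  m <- length(sel)
  n1 <- length(heps_a); n2 <- length(heps_b)
  stack <- function(hs, ch) t(vapply(hs, function(h) h$waveforms[ch, sel],
                                     numeric(m)))
  nch <- length(labels)
  Fm <- matrix(NA_real_, nch, m); Pm <- matrix(NA_real_, nch, m)
  win_rows <- list()
  for (ch in seq_len(nch)) {
    A <- stack(heps_a, ch); B <- stack(heps_b, ch)
    ma <- colMeans(A); mb <- colMeans(B)
    gm <- (n1 * ma + n2 * mb) / (n1 + n2)
    ssb <- n1 * (ma - gm)^2 + n2 * (mb - gm)^2
    ssw <- colSums(sweep(A, 2, ma)^2) + colSums(sweep(B, 2, mb)^2)
    dfw <- n1 + n2 - 2
    Fv <- (ssb / 1) / (ssw / dfw)
    p <- stats::pf(Fv, 1, dfw, lower.tail = FALSE)
    p_corr <- pmin(1, p * m)
    Fm[ch, ] <- Fv; Pm[ch, ] <- p_corr
    sig <- !is.na(p_corr) & p_corr < alpha
    r <- rle(sig)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      i1 <- sel[starts[j]]; i2 <- sel[ends[j]]
      if (t_ms[i2] - t_ms[i1] >= min_win_ms)
        win_rows[[length(win_rows) + 1L]] <- data.frame(
          channel = labels[ch], t_start_ms = t_ms[i1], t_end_ms = t_ms[i2],
          p_corrected = min(p_corr[starts[j]:ends[j]]))
    }
  }
  out <- if (length(win_rows)) do.call(rbind, win_rows)
  else data.frame(channel = character(), t_start_ms = numeric(),
                  t_end_ms = numeric(), p_corrected = numeric())
  attr(out, "F_matrix") <- Fm
  attr(out, "p_matrix") <- Pm
  attr(out, "time_ms") <- t_ms[sel]
  out
}
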