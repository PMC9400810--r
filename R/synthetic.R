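#' Synthetic ECG+EEG cohort specification
#'
#' Describes a two-group cohort ("RE-like" vs "control-like") of simultaneous
#' single-lead ECG and 19-channel 10/20 EEG recordings. A single latent vagal
#' "tone" scalar per subject (standard normal) drives both the depth of the
#' 0.25 Hz (high-frequency, respiratory-band) RR modulation and the per-band
#' EEG power, so heart-brain coupling of either sign can be planted and
#' recovered downstream.
#'
#' Coupling slopes are in dB of band power per unit tone; positive slopes
#' emulate the coupling regime reported for refractory-epilepsy-like cohorts,
#' negative slopes the control-like regime.
#'
#' @param n_per_group named integer vector, subjects per group
#' @param duration_s recording length in seconds (default 600 = 10 min)
#' @param fs sampling rate in Hz (default 256)
#' @param rr_mean_ms mean RR interval in ms
#' @param rr_lf_amp_ms amplitude of the 0.10 Hz RR modulation in ms
#' @param rr_hf_amp_base_ms baseline amplitude of the 0.25 Hz RR modulation
#' @param rr_jitter_ms SD of white beat-to-beat jitter in ms
#' @param tone_coupling_gain ms of extra 0.25 Hz modulation depth per unit tone
#' @param band_coupling_slope named list, one entry per group; each entry a
#'   single number or a named vector by band (dB per unit tone)
#' @param base_power_db named vector, baseline band power in dB (uV^2/Hz)
#' @param hep_amp_uV named vector, injected heartbeat-evoked amplitude per group
#' @param hep_latency_ms length-2 window (ms after R peak) of the injected
#'   half-sine component
#' @param cfa_gain cardiac-field bleed factor, uV of EEG per mV of ECG
#' @param noise_sd_uV broadband EEG sensor noise SD
#' @param ecg_noise_sd_mV ECG white noise SD
#' @param ecg_wander_amp_mV ECG baseline wander amplitude
#' @param seed integer RNG seed
#' @return an object of class `cohort_spec`
#' @export
cohort_spec <- function(n_per_group = c(re_like = 11, control_like = 7),
                        duration_s = 600, fs = 256,
                        rr_mean_ms = 850, rr_lf_amp_ms = 30,
                        rr_hf_amp_base_ms = 40, rr_jitter_ms = 5,
                        tone_coupling_gain = 15,
                        band_coupling_slope = list(re_like = 2,
                                                   control_like = -2),
                        base_power_db = c(delta = 15, theta = 12, alpha1 = 12,
                                          alpha2 = 10, beta = 6),
                        hep_amp_uV = c(re_like = 5, control_like = 2),
                        hep_latency_ms = c(400, 500),
                        cfa_gain = 2, noise_sd_uV = 10,
                        ecg_noise_sd_mV = 0.02, ecg_wander_amp_mV = 0.05,
                        seed = 1L) {
  if (abs(duration_s * fs - round(duration_s * fs)) > 1e-9)
    stop("duration_s * fs must be an integer sample count")
  if (rr_mean_ms <= rr_lf_amp_ms + rr_hf_amp_base_ms)
    stop("rr_mean_ms must exceed rr_lf_amp_ms + rr_hf_amp_base_ms")
  spec <- list(n_per_group = n_per_group, duration_s = duration_s, fs = fs,
               rr_mean_ms = rr_mean_ms, rr_lf_amp_ms = rr_lf_amp_ms,
               rr_hf_amp_base_ms = rr_hf_amp_base_ms,
               rr_jitter_ms = rr_jitter_ms,
               tone_coupling_gain = tone_coupling_gain,
               band_coupling_slope = band_coupling_slope,
               base_power_db = base_power_db,
               hep_amp_uV = hep_amp_uV, hep_latency_ms = hep_latency_ms,
               cfa_gain = cfa_gain, noise_sd_uV = noise_sd_uV,
               ecg_noise_sd_mV = ecg_noise_sd_mV,
               ecg_wander_amp_mV = ecg_wander_amp_mV,
               seed = as.integer(seed))
  class(spec) <- "cohort_spec"
  spec
}

# resolve the coupling slope for (group, band); entries may be scalar or
# band-named vectors
coupling_slope <- function(spec, group, band) {
  s <- spec$band_coupling_slope[[group]]
  if (is.null(s)) stop("no coupling slope for group ", group)
  if (length(s) == 1L && is.null(names(s))) return(as.numeric(s))
  if (!band %in% names(s)) stop("no coupling slope for band ", band)
  as.numeric(s[[band]])
}

#' Generate an RR interval series with LF/HF oscillatory structure
#'
#' RR(k) = mean + lf_amp sin(2 pi 0.10 t) + depth sin(2 pi 0.25 t) + jitter,
#' where depth = max(0, hf_base + gain * tone) and the modulators are
#' evaluated at the predicted beat time (the exact terminating time is
#' implicit in RR(k) itself). Beat times are cumulative sums; the series is
#' truncated at `duration_s`. Uses the current RNG state.
#'
#' @param spec a `cohort_spec`
#' @param tone_u latent vagal tone for this subject (unitless)
#' @return list with `rr_ms` (intervals) and `beat_times_s`
#' @export
generate_rr_series <- function(spec, tone_u) {
  stopifnot(is.finite(tone_u))
  depth <- max(0, spec$rr_hf_amp_base_ms + spec$tone_coupling_gain * tone_u)
  n_max <- ceiling(spec$duration_s * 1000 / (spec$rr_mean_ms -
           spec$rr_lf_amp_ms - depth - 6 * max(spec$rr_jitter_ms, 1))) + 10L
  jit <- if (spec$rr_jitter_ms > 0) stats::rnorm(n_max, 0, spec$rr_jitter_ms)
         else numeric(n_max)
  rr <- numeric(n_max); tt <- numeric(n_max)
  t_cur <- 0; k <- 0L
  repeat {
    t_pred <- t_cur + spec$rr_mean_ms / 1000
    r <- spec$rr_mean_ms +
      spec$rr_lf_amp_ms * sin(2 * pi * 0.10 * t_pred) +
      depth * sin(2 * pi * 0.25 * t_pred) + jit[k + 1L]
    if (r <= 300 || r >= 2000)
      stop("spec generates RR interval outside (300, 2000) ms: ", round(r))
    t_new <- t_cur + r / 1000
    if (t_new > spec$duration_s) break
    k <- k + 1L
    rr[k] <- r; tt[k] <- t_new
    t_cur <- t_new
  }
  list(rr_ms = rr[seq_len(k)], beat_times_s = tt[seq_len(k)])
}

# fixed PQRST morphology: sum of Gaussians (amplitude mV, centre s, width s);
# R is the global per-beat maximum by construction
.pqrst <- data.frame(
  wave = c("P", "Q", "R", "S", "T"),
  amp  = c(0.12, -0.10, 1.00, -0.15, 0.35),
  mu   = c(-0.20, -0.030, 0.000, 0.030, 0.250),
  sd   = c(0.030, 0.010, 0.012, 0.012, 0.045))

#' Synthesize a single-lead ECG trace from beat times
#'
#' Sum of per-beat Gaussian PQRST templates plus slow baseline wander and
#' white noise. Uses the current RNG state.
#'
#' @param beat_times_s strictly increasing beat (R wave) times in seconds
#' @param fs sampling rate in Hz
#' @param duration_s trace length in seconds
#' @param noise_sd_mV white noise SD
#' @param wander_amp_mV baseline wander amplitude (0.15 Hz sinusoid)
#' @return single-channel `recording` labelled "ECG", units mV
#' @export
synthesize_ecg <- function(beat_times_s, fs, duration_s,
                           noise_sd_mV = 0.02, wander_amp_mV = 0.05) {
  if (is.unsorted(beat_times_s, strictly = TRUE))
    stop("beat times must be strictly increasing")
  if (length(beat_times_s) > 1 && min(diff(beat_times_s)) < 0.3)
    stop("overlapping PQRST templates: RR < 300 ms")
  n <- round(duration_s * fs)
  x <- numeric(n)
  half_w <- round(0.45 * fs)
  tpl_off <- seq(-half_w, half_w)
  for (bt in beat_times_s) {
    ctr <- round(bt * fs) + 1L
    idx <- ctr + tpl_off
    keep <- idx >= 1L & idx <= n
    tau <- tpl_off[keep] / fs
    tpl <- numeric(length(tau))
    for (w in seq_len(nrow(.pqrst)))
      tpl <- tpl + .pqrst$amp[w] *
        exp(-0.5 * ((tau - .pqrst$mu[w]) / .pqrst$sd[w])^2)
    x[idx[keep]] <- x[idx[keep]] + tpl
  }
  tgrid <- seq_len(n) / fs
  if (wander_amp_mV > 0) x <- x + wander_amp_mV * sin(2 * pi * 0.15 * tgrid)
  if (noise_sd_mV > 0) x <- x + stats::rnorm(n, 0, noise_sd_mV)
  recording(matrix(x, nrow = 1), fs, "ECG", units = "mV")
}

# heartbeat-evoked topography: dipolar, maximal fronto-central with
# posterior inversion, re-centred to exactly zero mean so an average
# reference preserves it; scaled so the maximal site has weight 1.
# hep_amp_uV is therefore the amplitude at the fronto-polar maximum.
.hep_topography <- function() {
  w <- c(Fp1 = 1, Fp2 = 1, F7 = 1, F3 = 1, Fz = 1, F4 = 1, F8 = 1,
         T3 = 0.2, C3 = 0.8, Cz = 0.8, C4 = 0.8, T4 = 0.2,
         T5 = -0.5, P3 = -0.7, Pz = -0.7, P4 = -0.7, T6 = -0.5,
         O1 = -0.9, O2 = -0.9)
  w <- w - mean(w)
  w / max(w)
}

# channel -> lobe for coupling-slope lookup (midline channels take their
# lobe's slope; they sit outside the ROI map but still need band content)
.channel_lobe <- c(Fp1 = "F", Fp2 = "F", F7 = "F", F3 = "F", Fz = "F",
                   F4 = "F", F8 = "F", T3 = "T", C3 = "C", Cz = "C",
                   C4 = "C", T4 = "T", T5 = "T", P3 = "P", Pz = "P",
                   P4 = "P", T6 = "T", O1 = "O", O2 = "O")

#' Synthesize a 19-channel EEG recording with planted band power,
#' heartbeat-evoked component and cardiac-field bleed
#'
#' Each channel is a sum over the five canonical bands of band-pass-filtered
#' white noise, closed-loop calibrated so that the Welch band power (as the
#' band-power module computes it, 4-s Hamming segments, 0% overlap) hits
#' `base_power_db[band] + slope(group, band) * tone_u`. On top of that: a
#' half-sine deflection of `hep_amp_uV[group]` in the `hep_latency_ms` window
#' after every R peak, spread over the scalp with a fixed zero-mean dipolar
#' topography (fronto-central maximum of weight 1, posterior inversion, so
#' an average reference preserves it); `cfa_gain` times the ECG trace; and
#' white sensor noise. Uses the current RNG state.
#'
#' @param spec a `cohort_spec`
#' @param tone_u latent tone
#' @param group_label group name (must index `spec$hep_amp_uV` and
#'   `spec$band_coupling_slope`)
#' @param true_r_peaks R-peak sample indices (1-based)
#' @param ecg a single-channel ECG `recording` (mV)
#' @return list: `recording` (19 channels, uV) and `true_band_power_db`
#'   (band x ROI-cell data frame of calibration targets)
#' @export
synthesize_eeg <- function(spec, tone_u, group_label, true_r_peaks, ecg) {
  fs <- spec$fs
  n <- round(spec$duration_s * fs)
  chans <- montage_1020()
  bands <- eeg_bands()
  # band shaping is done spectrally (one FFT per channel, one inverse FFT
  # per band) with the squared Butterworth magnitude, i.e. the same
  # zero-phase response filtfilt would apply; the closed-loop Welch
  # calibration below absorbs any residual shape difference
  fgrid <- (seq_len(n) - 1) * fs / n
  fgrid <- pmin(fgrid, fs - fgrid)        # two-sided grid folded
  masks <- lapply(seq_len(nrow(bands)), function(i) {
    flt <- butter_filter(4, c(bands$lo[i], bands$hi[i]), fs, "pass")
    Mod(freq_response(flt$b, flt$a, fgrid, fs))^2
  })
  if (n_samples(ecg) != n)
    stop("ECG trace length does not match spec duration")
  nch <- length(chans)
  acc <- matrix(0, n, nch)              # samples x channels
  target_db <- matrix(NA_real_, nrow(bands), nch,
                      dimnames = list(bands$band, chans))
  nperseg <- round(4 * fs)
  w <- hamming_window(nperseg)
  wscale <- 1 / (fs * sum(w^2))
  seg_starts <- seq(1L, n - nperseg + 1L, by = nperseg)
  for (bi in seq_len(nrow(bands))) {
    tgt_db <- spec$base_power_db[[bands$band[bi]]] +
      coupling_slope(spec, group_label, bands$band[bi]) * tone_u
    if (!is.finite(tgt_db)) stop("non-finite target band power")
    # independent noise per band and channel: overlapping filter skirts
    # must add incoherently or band-edge power is inflated
    Wf <- stats::mvfft(matrix(stats::rnorm(n * nch), n, nch))
    B <- Re(stats::mvfft(Wf * masks[[bi]], inverse = TRUE)) / n
    # closed-loop calibration: Welch band density of each channel's band
    # trace, computed exactly as the band-power module computes it
    # (Hamming, 4-s segments, 0% overlap, segment means removed)
    segs <- do.call(rbind, lapply(seg_starts, function(s)
      B[s:(s + nperseg - 1L), , drop = FALSE]))
    dim(segs) <- c(nperseg, length(seg_starts) * nch)
    segs <- sweep(segs, 2, colMeans(segs))
    nfreq <- nperseg %/% 2L + 1L
    P <- Mod(stats::mvfft(segs * w)[seq_len(nfreq), , drop = FALSE])^2 *
      wscale
    dim(P) <- c(nfreq, length(seg_starts), nch)
    fgrid1 <- (seq_len(nfreq) - 1) * fs / nperseg
    insel <- fgrid1 >= bands$lo[bi] & fgrid1 < bands$hi[bi]
    dbl <- ifelse(fgrid1 %in% c(0, fs / 2), 1, 2)
    have <- apply(P[insel, , , drop = FALSE] * dbl[insel], 3, mean)
    acc <- acc + B * rep(sqrt(10^(tgt_db / 10) / have), each = n)
    target_db[bi, ] <- tgt_db
  }
  out <- t(acc)
  amp <- spec$hep_amp_uV[[group_label]]
  if (amp != 0 && length(true_r_peaks)) {
    o1 <- round(spec$hep_latency_ms[1] / 1000 * fs)
    o2 <- round(spec$hep_latency_ms[2] / 1000 * fs)
    shape <- amp * sin(pi * seq(0, 1, length.out = o2 - o1 + 1))
    topo <- .hep_topography()[chans]
    for (p in true_r_peaks) {
      idx <- (p + o1):(p + o2)
      keep <- idx >= 1L & idx <= n
      if (any(keep))
        out[, idx[keep]] <- out[, idx[keep], drop = FALSE] +
          outer(topo, shape[keep])
    }
  }
  if (spec$cfa_gain != 0)
    out <- out + matrix(spec$cfa_gain * ecg$samples[1, ], length(chans), n,
                        byrow = TRUE)
  if (spec$noise_sd_uV > 0)
    out <- out + matrix(stats::rnorm(length(chans) * n, 0, spec$noise_sd_uV),
                        length(chans), n)
  rois <- eeg_rois()
  tb <- do.call(rbind, lapply(seq_len(nrow(rois)), function(ri) {
    members <- rois$channels[[ri]]
    data.frame(band = bands$band,
               roi = rois$roi[ri], hemisphere = rois$hemisphere[ri],
               power_db = rowMeans(target_db[, members, drop = FALSE]))
  }))
  rownames(tb) <- NULL
  list(recording = recording(out, fs, chans, units = "uV"),
       true_band_power_db = tb)
}

#' Generate a full synthetic cohort
#'
#' Deterministic given `spec$seed`: each subject gets a sub-seed drawn once
#' from the cohort seed, so recordings are byte-identical across runs and
#' independent of output location. Ground truth (tone, R peaks, band-power
#' targets, HRV of the emitted RR series) is carried in the manifest.
#'
#' @param spec a `cohort_spec`
#' @param out_dir optional directory; when given, one EDF per subject plus
#'   `manifest.json` and ground-truth CSVs are written there
#' @return list with `subjects` (each: id, group, tone_u, recording,
#'   true_r_peaks, true_band_power_db, true_hrv) and `manifest`
#' @export
generate_cohort <- function(spec, out_dir = NULL) {
  groups <- rep(names(spec$n_per_group), spec$n_per_group)
  n_tot <- length(groups)
  ids <- sprintf("%s%02d", ifelse(groups == names(spec$n_per_group)[1],
                                  "S", "C"),
                 unlist(lapply(spec$n_per_group, seq_len)))
  set.seed(spec$seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_tot)
  subjects <- vector("list", n_tot)
  for (i in seq_len(n_tot)) {
    set.seed(sub_seeds[i])
    tone_u <- stats::rnorm(1)
    rrs <- generate_rr_series(spec, tone_u)
    ecg <- synthesize_ecg(rrs$beat_times_s, spec$fs, spec$duration_s,
                          spec$ecg_noise_sd_mV, spec$ecg_wander_amp_mV)
    r_peaks <- round(rrs$beat_times_s * spec$fs) + 1L
    r_peaks <- r_peaks[r_peaks >= 1L & r_peaks <= n_samples(ecg)]
    eeg <- synthesize_eeg(spec, tone_u, groups[i], r_peaks, ecg)
    rec <- recording(rbind(eeg$recording$samples, ecg$samples),
                     spec$fs, c(eeg$recording$labels, "ECG"),
                     c(eeg$recording$units, "mV"))
    true_hrv <- c(compute_time_domain(rrs$rr_ms),
                  list(hf_ms2 = tryCatch(
                    compute_hf_power(rrs$rr_ms, rrs$beat_times_s),
                    error = function(e) NA_real_)))
    subjects[[i]] <- list(id = ids[i], group = groups[i], tone_u = tone_u,
                          seed = sub_seeds[i], recording = rec,
                          true_r_peaks = r_peaks,
                          true_band_power_db = eeg$true_band_power_db,
                          true_hrv = true_hrv)
  }
  manifest <- list(
    spec = unclass(spec),
    subjects = lapply(subjects, function(s)
      list(id = s$id, group = s$group, seed = s$seed, tone_u = s$tone_u,
           n_beats = length(s$true_r_peaks),
           true_hrv = s$true_hrv,
           edf = paste0(s$id, ".edf"))))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (s in subjects)
      write_edf(s$recording, file.path(out_dir, paste0(s$id, ".edf")),
                patient_id = s$id, recording_id = s$group)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    gt <- do.call(rbind, lapply(subjects, function(s)
      cbind(subject = s$id, group = s$group, s$true_band_power_db)))
    utils::write.csv(gt, file.path(out_dir, "true_band_power.csv"),
                     row.names = FALSE)
    hrv_gt <- do.call(rbind, lapply(subjects, function(s)
      data.frame(subject = s$id, group = s$group,
                 sdnn_ms = s$true_hrv$sdnn_ms, rmssd_ms = s$true_hrv$rmssd_ms,
                 sd1_ms = s$true_hrv$sd1_ms, hf_ms2 = s$true_hrv$hf_ms2)))
    utils::write.csv(hrv_gt, file.path(out_dir, "true_hrv.csv"),
                     row.names = FALSE)
  }
  list(subjects = subjects, manifest = manifest)
}
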