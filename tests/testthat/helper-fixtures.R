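# shared fixtures; everything is generated in code, nothing is stored

# a small, fast cohort spec for round-trip tests (scaled-down duration;
# physiology parameters are the package defaults)
quick_spec <- function(duration_s = 64, ...) {
  cohort_spec(n_per_group = c(re_like = 3, control_like = 3),
              duration_s = duration_s, ...)
}

# noise-free single subject: RR series + ECG + true peak indices
quick_subject <- function(duration_s = 64, tone_u = 0, noise_sd_mV = 0,
                          wander_amp_mV = 0, spec = quick_spec(duration_s)) {
  rr <- generate_rr_series(spec, tone_u)
  ecg <- synthesize_ecg(rr$beat_times_s, spec$fs, duration_s,
                        noise_sd_mV = noise_sd_mV,
                        wander_amp_mV = wander_amp_mV)
  list(spec = spec, rr = rr, ecg = ecg,
       true_peaks = round(rr$beat_times_s * spec$fs) + 1L)
}

# an rpeak_train at given beat times (seconds)
peaks_at <- function(times_s, fs = 256) {
  structure(list(peak_indices = round(times_s * fs) + 1L, fs = fs),
            class = "rpeak_train")
}

# nn_series built directly from intervals
nn_from <- function(intervals_ms, t0 = 0) {
  structure(list(intervals_ms = intervals_ms,
                 times_s = t0 + cumsum(intervals_ms) / 1000,
                 n_rejected = 0L), class = "nn_series")
}

# single-channel recording from a vector
one_channel <- function(x, fs = 256, label = "Cz") {
  recording(matrix(x, nrow = 1), fs, label, units = "uV")
}

# detection scoring against ground truth (tolerance in samples)
score_detection <- function(detected, truth, tol = 13) {
  d <- vapply(detected, function(i) min(abs(truth - i)), numeric(1))
  tp <- sum(d <= tol)
  fp <- length(detected) - tp
  fn <- length(truth) -
    sum(vapply(truth, function(t) any(abs(detected - t) <= tol), logical(1)))
  list(f1 = 2 * tp / (2 * tp + fp + fn), median_err = stats::median(d),
       tp = tp, fp = fp, fn = fn)
}

# brute-force permutation matrix, written independently of the package's
# recursive generator (iterative Steinhaus-Johnson-Trotter-free approach via
# repeated insertion) -- used as the oracle for exact Spearman enumeration
oracle_permutations <- function(n) {
  rows <- list(1L)
  for (k in 2:n) {
    rows <- unlist(lapply(rows, function(p) {
      lapply(seq_len(k), function(pos) append(p, k, after = pos - 1L))
    }), recursive = FALSE)
  }
  do.call(rbind, rows)
}
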