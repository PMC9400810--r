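test_that("constant-rate limit: exactly one beat per second", {
  spec <- cohort_spec(rr_mean_ms = 1000, rr_lf_amp_ms = 0,
                      rr_hf_amp_base_ms = 0, rr_jitter_ms = 0,
                      tone_coupling_gain = 0, duration_s = 600)
  rr <- generate_rr_series(spec, tone_u = 0)
  expect_length(rr$rr_ms, 600)
  expect_true(all(rr$rr_ms == 1000))
  expect_equal(rr$beat_times_s, as.numeric(1:600))
})

test_that("RMSSD of a pure HF-modulated series matches the direct formula", {
  spec <- cohort_spec(rr_mean_ms = 1000, rr_lf_amp_ms = 0,
                      rr_hf_amp_base_ms = 50, rr_jitter_ms = 0,
                      tone_coupling_gain = 0, duration_s = 300)
  rr <- generate_rr_series(spec, tone_u = 0)
  # independent brute-force pass over successive differences
  d <- rr$rr_ms[-1] - rr$rr_ms[-length(rr$rr_ms)]
  oracle <- sqrt(sum(d^2) / length(d))
  expect_equal(compute_time_domain(rr$rr_ms)$rmssd_ms, oracle,
               tolerance = 1e-12)
})

test_that("HF power increases with latent tone", {
  spec <- quick_spec(duration_s = 120)
  set.seed(5)
  rr_lo <- generate_rr_series(spec, tone_u = -1)
  rr_hi <- generate_rr_series(spec, tone_u = +1)
  hf_lo <- compute_hf_power(rr_lo$rr_ms, rr_lo$beat_times_s)
  hf_hi <- compute_hf_power(rr_hi$rr_ms, rr_hi$beat_times_s)
  expect_gt(hf_hi, hf_lo)
})

test_that("RR intervals outside (300, 2000) ms are rejected at generation", {
  spec <- cohort_spec(rr_mean_ms = 2000, rr_lf_amp_ms = 30,
                      rr_hf_amp_base_ms = 40, duration_s = 60)
  expect_error(generate_rr_series(spec, tone_u = 0), "outside")
})

test_that("single-beat ECG peaks at the beat time; beats are countable", {
  fs <- 256
  ecg <- synthesize_ecg(1, fs, 3, noise_sd_mV = 0, wander_amp_mV = 0)
  expect_lte(abs(which.max(ecg$samples[1, ]) - (round(1 * fs) + 1)), 1)
  # 60 bpm, 60 s: threshold count of local maxima above half the R amplitude
  ecg2 <- synthesize_ecg(1:60, fs, 61, noise_sd_mV = 0, wander_amp_mV = 0)
  x <- ecg2$samples[1, ]
  n <- length(x)
  locmax <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  expect_equal(sum(x[locmax] > 0.5), 60)
  expect_error(synthesize_ecg(c(1, 1.2), fs, 3), "RR < 300")
})

test_that("EEG calibration: single-band target is recovered, others stay at the floor", {
  spec <- cohort_spec(duration_s = 64, noise_sd_uV = 0, cfa_gain = 0,
                      hep_amp_uV = c(re_like = 0, control_like = 0),
                      base_power_db = c(delta = -40, theta = -40, alpha1 = 15,
                                        alpha2 = -40, beta = -40),
                      band_coupling_slope = list(re_like = 0,
                                                 control_like = 0))
  set.seed(21)
  rr <- generate_rr_series(spec, 0)
  ecg <- synthesize_ecg(rr$beat_times_s, spec$fs, spec$duration_s, 0, 0)
  eeg <- synthesize_eeg(spec, 0, "re_like", integer(0), ecg)
  psd <- welch_psd(eeg$recording$samples[1, ], spec$fs)
  a1 <- 10 * log10(band_mean_density(psd, 8, 10))
  dl <- 10 * log10(band_mean_density(psd, 1, 4))
  expect_equal(a1, 15, tolerance = 1)
  expect_lt(dl, -20)
})

test_that("injected heartbeat-evoked component follows the averaging law", {
  spec <- cohort_spec(duration_s = 120, noise_sd_uV = 10, cfa_gain = 0,
                      base_power_db = c(delta = -40, theta = -40,
                                        alpha1 = -40, alpha2 = -40,
                                        beta = -40),
                      hep_amp_uV = c(re_like = 5, control_like = 0),
                      band_coupling_slope = list(re_like = 0,
                                                 control_like = 0))
  set.seed(31)
  rr <- generate_rr_series(spec, 0)
  ecg <- synthesize_ecg(rr$beat_times_s, spec$fs, spec$duration_s, 0, 0)
  rp <- round(rr$beat_times_s * spec$fs) + 1L
  eeg <- synthesize_eeg(spec, 0, "re_like", rp, ecg)
  # raw average over beats in the injected window, one channel
  x <- eeg$recording$samples[1, ]
  o1 <- round(0.4 * spec$fs); o2 <- round(0.5 * spec$fs)
  rp_ok <- rp[rp + o2 <= length(x)]
  m <- rowMeans(vapply(rp_ok, function(p) x[(p + o1):(p + o2)],
                       numeric(o2 - o1 + 1)))
  injected <- 5 * sin(pi * seq(0, 1, length.out = o2 - o1 + 1))
  tol <- 3 * 10 / sqrt(length(rp_ok))
  expect_lt(abs(mean(m) - mean(injected)), tol)
})

test_that("cardiac-field bleed scales with cfa_gain", {
  spec0 <- cohort_spec(duration_s = 32, noise_sd_uV = 0, cfa_gain = 0,
                       hep_amp_uV = c(re_like = 0, control_like = 0))
  spec2 <- spec0; spec2$cfa_gain <- 2
  rr <- generate_rr_series(spec0, 0)
  ecg <- synthesize_ecg(rr$beat_times_s, spec0$fs, 32, 0, 0)
  set.seed(8); e0 <- synthesize_eeg(spec0, 0, "re_like", integer(0), ecg)
  set.seed(8); e2 <- synthesize_eeg(spec2, 0, "re_like", integer(0), ecg)
  bleed <- e2$recording$samples[1, ] - e0$recording$samples[1, ]
  expect_equal(bleed, 2 * ecg$samples[1, ], tolerance = 1e-12)
})

test_that("cohort generation is deterministic and writes one EDF per subject", {
  spec <- quick_spec(duration_s = 32, seed = 99)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  c1 <- generate_cohort(spec, out_dir = d1)
  c2 <- generate_cohort(spec, out_dir = d2)
  expect_length(c1$subjects, 6)
  expect_length(list.files(d1, pattern = "\\.edf$"), 6)
  expect_identical(c1$subjects[[4]]$recording$samples,
                   c2$subjects[[4]]$recording$samples)
  f <- function(d, s) unname(tools::md5sum(file.path(d, s)))
  for (s in paste0(c("S01", "C03"), ".edf"))
    expect_identical(f(d1, s), f(d2, s))
  # manifest carries ground truth for every subject
  expect_length(c1$manifest$subjects, 6)
  expect_true(all(vapply(c1$manifest$subjects,
                         function(s) is.finite(s$true_hrv$rmssd_ms),
                         logical(1))))
})

test_that("ground-truth RR stays within physiological bounds across tones", {
  spec <- quick_spec(duration_s = 32)
  set.seed(3)
  for (tone in c(-2.5, 0, 2.5)) {
    rr <- generate_rr_series(spec, tone)
    expect_true(all(rr$rr_ms > 300 & rr$rr_ms < 2000))
    expect_true(all(diff(rr$beat_times_s) > 0))
  }
})
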