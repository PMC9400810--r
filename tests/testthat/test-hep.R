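# single-channel helpers keep these tests fast; epoching is channel-agnostic

test_that("epoch index arithmetic matches the [-200, 600) ms contract", {
  fs <- 256
  x <- numeric(10 * fs)
  eeg <- one_channel(x, fs)
  pk <- structure(list(peak_indices = 1001L, fs = fs), class = "rpeak_train")
  ep <- epoch_heartbeats(eeg, pk, min_beats = 1)
  # 0-based sample 1000 -> epoch spans 0-based samples 949..1153 (205 samples)
  expect_equal(dim(ep$data)[3], 205L)
  expect_equal(range(ep$time_ms), c(-51, 153) / fs * 1000)
  expect_true(0 %in% ep$time_ms)
  expect_true(all(ep$data == 0))
  expect_equal(ep$rejected_trials, 0L)
})

test_that("epoching drops edge peaks, rejects large-amplitude trials, errors when too few", {
  fs <- 256
  set.seed(1)
  x <- rnorm(60 * fs, sd = 5)
  pk <- peaks_at(seq(1, 59, by = 1), fs)
  eeg <- one_channel(x, fs)
  ep <- suppressMessages(epoch_heartbeats(eeg, pk))
  expect_equal(ep$n_trials + ep$rejected_trials, 59L)
  # a sustained artifact in one beat's window (long enough to survive the
  # 15 Hz low-pass) -> exactly one more rejection
  x2 <- x; x2[round(30 * fs) + 10:110] <- 400
  ep2 <- suppressMessages(epoch_heartbeats(one_channel(x2, fs), pk))
  expect_equal(ep2$rejected_trials, ep$rejected_trials + 1L)
  expect_error(epoch_heartbeats(eeg, peaks_at(c(5, 6, 7), fs)), "at least 30")
})

test_that("averaging: exact cancellation, trial cap, baseline option", {
  fs <- 256
  ep <- structure(list(
    data = array(rep(c(1, -1), times = 205), c(1, 2, 205)),
    time_ms = (-51:153) / fs * 1000, fs = fs, n_trials = 2L,
    rejected_trials = 0L, labels = "Cz"), class = "hep_epochs")
  av <- average_hep(ep)
  expect_true(all(av$waveforms == 0))
  big <- structure(list(
    data = array(rnorm(1 * 600 * 205), c(1, 600, 205)),
    time_ms = (-51:153) / fs * 1000, fs = fs, n_trials = 600L,
    rejected_trials = 0L, labels = "Cz"), class = "hep_epochs")
  av179 <- average_hep(big, max_trials = 179)
  expect_equal(av179$n_trials_used, 179L)
  # baseline subtraction zeroes the baseline window mean
  avb <- average_hep(big, baseline = c(-200, -50))
  bsel <- avb$time_ms >= -200 & avb$time_ms <= -50
  expect_lt(abs(mean(avb$waveforms[1, bsel])), 1e-9)
})

test_that("averaging obeys the sqrt(N) law and commutes with low-pass", {
  fs <- 256
  set.seed(5)
  n_tr <- 600; sigma <- 10
  sig <- 5 * sin(pi * seq(0, 1, length.out = 26))
  s_t <- numeric(205); s_t[130:155] <- sig
  dat <- array(rnorm(n_tr * 205, sd = sigma), c(1, n_tr, 205))
  dat <- sweep(dat, 3, s_t, "+")
  ep <- structure(list(data = dat, time_ms = (-51:153) / fs * 1000, fs = fs,
                       n_trials = n_tr, rejected_trials = 0L, labels = "Cz"),
                  class = "hep_epochs")
  av <- average_hep(ep)
  dev <- av$waveforms[1, ] - s_t
  expect_equal(sd(dev), sigma / sqrt(n_tr), tolerance = 0.15 * sigma / sqrt(n_tr))
  # linearity: average of filtered epochs == filtered average
  lp <- butter_filter(4, 15, fs, "low")
  filt_then_avg <- rowMeans(apply(dat[1, , ], 1, function(tr)
    filtfilt(lp$b, lp$a, tr)))
  avg_then_filt <- filtfilt(lp$b, lp$a, av$waveforms[1, ])
  expect_equal(filt_then_avg, avg_then_filt, tolerance = 1e-9)
})

test_that("injected component round-trips through epoching at the right latency", {
  spec <- cohort_spec(duration_s = 90, noise_sd_uV = 2, cfa_gain = 0,
                      base_power_db = c(delta = -40, theta = -40, alpha1 = -40,
                                        alpha2 = -40, beta = -40),
                      hep_amp_uV = c(re_like = 5, control_like = 0),
                      band_coupling_slope = list(re_like = 0, control_like = 0))
  set.seed(6)
  rr <- generate_rr_series(spec, 0)
  ecg <- synthesize_ecg(rr$beat_times_s, spec$fs, spec$duration_s, 0, 0)
  rp <- round(rr$beat_times_s * spec$fs) + 1L
  eeg <- synthesize_eeg(spec, 0, "re_like", rp, ecg)
  pk <- structure(list(peak_indices = rp, fs = spec$fs), class = "rpeak_train")
  ep <- suppressMessages(epoch_heartbeats(eeg$recording, pk))
  av <- average_hep(ep)
  pk_t <- av$time_ms[which.max(av$waveforms[1, ])]
  expect_gt(pk_t, 400); expect_lt(pk_t, 500)
  expect_equal(max(av$waveforms[1, ]), 5, tolerance = 1)
})

mk_subject_hep <- function(mu, sd_subj, time_ms, labels = "Cz") {
  structure(list(waveforms = matrix(mu + rnorm(length(time_ms), 0, sd_subj),
                                    1, length(time_ms)),
                 time_ms = time_ms, n_trials_used = 60L, labels = labels,
                 baseline = NULL),
            class = "hep_average")
}

test_that("group comparison: F equals t^2, windows confined to TOI, effects found", {
  fs <- 256
  time_ms <- (-51:153) / fs * 1000
  set.seed(8)
  mu_eff <- numeric(205); sel <- time_ms >= 400 & time_ms <= 500
  mu_eff[sel] <- 5
  ha <- lapply(1:11, function(i) mk_subject_hep(mu_eff, 1, time_ms))
  hb <- lapply(1:7, function(i) mk_subject_hep(0, 1, time_ms))
  win <- compare_groups_hep(ha, hb)
  expect_gt(nrow(win), 0)
  expect_true(all(win$t_start_ms >= 350 & win$t_end_ms <= 600))
  expect_true(any(win$t_start_ms <= 500 & win$t_end_ms >= 400))
  # F == t^2 at every tested sample
  A <- t(vapply(ha, function(h) h$waveforms[1, sel2 <- time_ms >= 350 & time_ms <= 600],
                numeric(sum(time_ms >= 350 & time_ms <= 600))))
  B <- t(vapply(hb, function(h) h$waveforms[1, time_ms >= 350 & time_ms <= 600],
                numeric(sum(time_ms >= 350 & time_ms <= 600))))
  Fm <- attr(win, "F_matrix")
  tsq <- vapply(seq_len(ncol(A)), function(j)
    unname(stats::t.test(A[, j], B[, j], var.equal = TRUE)$statistic^2),
    numeric(1))
  expect_equal(Fm[1, ], tsq, tolerance = 1e-9)
  expect_error(compare_groups_hep(ha[1], hb), "at least 2")
})
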