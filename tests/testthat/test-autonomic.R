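test_that("rmssd closed forms", {
  expect_equal(rmssd(c(800, 800, 800, 800)), 0)
  expect_equal(rmssd(c(800, 820, 800, 820)), 20)
  # sinusoidally modulated intervals against the closed form
  for (a in c(15, 30, 60)) {
    ibi_s <- 0.8
    f <- 0.25
    nn <- 800 + a * sin(2 * pi * f * ibi_s * seq_len(200))
    expect_equal(rmssd(nn), oracle_rmssd_sin(a, f, ibi_s), tolerance = 0.05)
  }
  expect_error(rmssd(c(800)), "at least 2")
})

test_that("rmssd is shift invariant and difference-scale linear", {
  set.seed(8)
  nn <- 800 + rnorm(100, sd = 30)
  expect_equal(rmssd(nn + 150), rmssd(nn), tolerance = 1e-9)
  expect_equal(rmssd(800 + 3 * (nn - 800)), 3 * rmssd(nn), tolerance = 1e-9)
})

test_that("interval screening drops artifacts", {
  nn <- c(rep(800, 20), 250, rep(800, 20), 2500, rep(800, 5))
  out <- screen_nn(nn)
  expect_false(any(out %in% c(250, 2500)))
  expect_equal(length(out), 45)
  # a 40% local jump is screened as ectopy
  nn2 <- c(rep(800, 10), 800 * 1.4, rep(800, 10))
  expect_equal(length(screen_nn(nn2)), 20)
})

test_that("pulse detection recovers synthetic beats", {
  p <- synth_ppg(duration_s = 60, mean_ibi_ms = 800, rsa_amp_ms = 0, seed = 3)
  b <- detect_pulses(p$recording)
  expect_lte(abs(length(b$beat_times_s) - length(p$beat_times_s)), 1)
  err_ms <- vapply(p$beat_times_s, function(tt)
    min(abs(b$beat_times_s - tt)) * 1000, numeric(1))
  expect_lt(mean(err_ms), 10)
})

test_that("pulse detection tolerates 10 dB noise", {
  clean <- synth_ppg(duration_s = 120, mean_ibi_ms = 800, rsa_amp_ms = 40,
                     jitter_ms = 10, seed = 4)
  snr_sd <- sd(clean$recording$samples[, 1]) / sqrt(10)
  p <- synth_ppg(duration_s = 120, mean_ibi_ms = 800, rsa_amp_ms = 40,
                 jitter_ms = 10, noise_sd = snr_sd, seed = 4)
  b <- detect_pulses(p$recording)
  err_ms <- vapply(p$beat_times_s, function(tt)
    min(abs(b$beat_times_s - tt)) * 1000, numeric(1))
  expect_lt(mean(err_ms), 10)
})

test_that("pulse detection contract cases", {
  flat <- new_recording(matrix(1, 512 * 40, 1), 512, "PPG", "PPG")
  expect_error(detect_pulses(flat), "periodicity|peaks")
  p <- synth_ppg(duration_s = 60, seed = 5)
  scaled <- p$recording
  scaled$samples <- scaled$samples * 37
  expect_equal(length(detect_pulses(scaled)$beat_times_s),
               length(detect_pulses(p$recording)$beat_times_s))
  short <- new_recording(matrix(rnorm(512 * 10), ncol = 1), 512, "PPG", "PPG")
  expect_error(detect_pulses(short), "30 s")
})

test_that("SCR detection counts injected events and respects the threshold", {
  flat <- new_recording(matrix(2, 512 * 90, 1), 512, "EDA", "EDA")
  expect_length(detect_scr(flat)$onset_times_s, 0)

  e <- synth_eda(duration_s = 360, n_scr = 8, amplitude_uS = 0.2, seed = 5)
  got <- detect_scr(e$recording, min_amplitude_uS = 0.05)
  expect_length(got$onset_times_s, 8)
  expect_equal(got$rate_per_min, 8 / 6)
  # detected onsets sit near the injected ones
  err <- vapply(e$scr_onsets_s, function(tt)
    min(abs(got$onset_times_s - tt)), numeric(1))
  expect_lt(max(err), 1.5)
  expect_length(detect_scr(e$recording, 0.3)$onset_times_s, 0)
  # count is non-increasing in threshold
  counts <- vapply(c(0.02, 0.05, 0.1, 0.25),
                   function(th) length(detect_scr(e$recording, th)$onset_times_s),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_error(detect_scr(trim_initial(e$recording, 330)), "60 s")
})
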