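test_that("window counts follow floor((duration - window)/shift) + 1", {
  sp <- sliding_psd(sine_eeg(10, duration_s = 300), 20, 1, 1)
  expect_equal(dim(sp$spectra)[1], 281)
  sp1 <- sliding_psd(sine_eeg(10, duration_s = 20), 20, 1, 1)
  expect_equal(dim(sp1$spectra)[1], 1)
  expect_error(sliding_psd(sine_eeg(10, duration_s = 10), 20, 1, 1),
               "shorter")
  # property over assorted geometries
  for (case in list(c(60, 20, 5), c(45, 15, 3), c(300, 20, 2))) {
    sp <- sliding_psd(sine_eeg(10, duration_s = case[1]),
                      window_s = case[2], shift_s = case[3], segment_s = 1)
    expect_equal(dim(sp$spectra)[1],
                 floor((case[1] - case[2]) / case[3]) + 1)
  }
})

test_that("a pure tone concentrates its spectrum in the right bin", {
  sp <- sliding_psd(sine_eeg(10, duration_s = 60), 20, 1, 1)
  for (w in c(1, 20, 41)) {
    p <- sp$spectra[w, , 1]
    expect_equal(sp$freq[which.max(p)], 10)
    # Hann taper spreads a line over +-1 bin; 9-11 Hz holds almost everything
    expect_gt(sum(p[sp$freq >= 9 & sp$freq <= 11]) / sum(p), 0.95)
  }
})

test_that("band fractions match analytic values", {
  sp <- sliding_psd(sine_eeg(10, duration_s = 60), 20, 1, 1)
  expect_gte(band_fraction(sp$freq, sp$spectra[1, , 1]), 0.95)
  sp20 <- sliding_psd(sine_eeg(20, duration_s = 60), 20, 1, 1)
  expect_lte(band_fraction(sp20$freq, sp20$spectra[1, , 1]), 0.05)
  # flat spectrum: alpha fraction = (13-8)/(30-4)
  freq <- 0:128
  expect_equal(band_fraction(freq, rep(1, 129)), 5 / 26, tolerance = 1e-12)
  # zero total power propagates as NA, never 0/0
  expect_true(is.na(band_fraction(freq, rep(0, 129))))
})

test_that("band fractions are scale invariant and monotone in alpha amplitude", {
  set.seed(42)
  base <- synth_eeg(duration_s = 30, modulation_depth = 0, seed = 7)
  s1 <- first_order_series(base)
  scaled <- base
  scaled$samples <- base$samples * 3.7
  s2 <- first_order_series(scaled)
  expect_equal(s1$values, s2$values, tolerance = 1e-9)

  fracs <- vapply(c(2, 6, 18), function(a) {
    eeg <- synth_eeg(duration_s = 30, alpha_amp = a, modulation_depth = 0,
                     seed = 11)
    mean(first_order_series(eeg)$values)
  }, numeric(1))
  expect_true(all(diff(fracs) > 0))
})

test_that("a stationary tone yields a near-constant alpha series", {
  set.seed(3)
  rec <- sine_eeg(10, duration_s = 120)
  rec$samples <- rec$samples + matrix(rnorm(length(rec$samples), sd = 0.05),
                                      nrow = nrow(rec$samples))
  ser <- first_order_series(rec)
  cv <- sd(ser$values[, 1]) / mean(ser$values[, 1])
  expect_lt(cv, 0.1)
  expect_equal(nrow(first_order_series(sine_eeg(10, 300))$values), 281)
})

test_that("amplitude modulation surfaces at the right series frequency", {
  t <- (seq_len(256 * 300) - 1) / 256
  x <- (1 + 0.8 * sin(2 * pi * 0.01 * t)) * sin(2 * pi * 10 * t)
  rec <- new_recording(matrix(rep(x, 6), ncol = 6), 256, eeg_channels(), "EEG")
  ser <- first_order_series(rec)
  # power series fluctuates; FFT oracle finds the 0.01 Hz line
  # (oracle grid spacing is 1/281 Hz, so allow one grid step)
  expect_lt(abs(oracle_peak_freq(ser$values[, 1], 1) - 0.01), 0.004)
})

test_that("welch_psd satisfies basic spectral identities", {
  set.seed(9)
  x <- rnorm(4096)
  ps <- welch_psd(x, fs = 256, seg_len = 256, window = "rect")
  # Parseval: integrated PSD recovers the variance
  expect_equal(sum(ps$psd) * 256 / 256, var(x), tolerance = 0.05)
  # band_power of a flat spectrum is level * bandwidth, any edges
  expect_equal(band_power(0:100, rep(2, 101), 7.25, 31.5), 2 * (31.5 - 7.25),
               tolerance = 1e-12)
})
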