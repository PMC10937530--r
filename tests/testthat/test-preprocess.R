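# evaluate the designed FIR's amplitude response at a frequency (oracle)
fir_gain <- function(spec, f_hz) {
  k <- seq_along(spec$coef) - 1
  Mod(sum(spec$coef * exp(-1i * 2 * pi * f_hz * k / spec$fs)))
}

# measured gain: amplitude ratio of a filtered sinusoid in the central region
measured_gain <- function(spec, f_hz, duration_s = 30) {
  rec <- sine_eeg(f_hz, duration_s = duration_s)
  out <- bandpass(rec, spec)
  core <- (5 * 256):(25 * 256)
  sqrt(mean(out$samples[core, 1]^2) / mean(rec$samples[core, 1]^2))
}

test_that("remove_offset zeroes channel means", {
  rec <- new_recording(cbind(rep(5, 99), rep(c(1, 2, 3), 33)), fs = 100,
                       modality = "PPG", channel_labels = c("a", "b"))
  out <- remove_offset(rec)
  expect_true(all(abs(colMeans(out$samples)) < 1e-12))
  expect_equal(out$samples[, 1], rep(0, 99), ignore_attr = TRUE)
  expect_equal(remove_offset(new_recording(c(1, 2, 3), 10, "x", "EDA"))$samples[, 1],
               c(-1, 0, 1), ignore_attr = TRUE)
  # idempotent on a zero-mean sinusoid
  s <- sine_eeg(10, duration_s = 2)
  expect_equal(remove_offset(s)$samples, s$samples, tolerance = 1e-9)
  empty <- new_recording(matrix(numeric(0), ncol = 1), 10, "x", "EDA")
  expect_error(remove_offset(empty), "empty")
})

test_that("bandpass passes alpha and rejects out-of-band energy", {
  spec <- filter_spec()
  g10 <- measured_gain(spec, 10)
  expect_gte(g10, 0.89)
  expect_lte(g10, 1.12)
  # design-response oracle agrees with the measurement
  expect_equal(g10, fir_gain(spec, 10), tolerance = 0.01)
  expect_lt(measured_gain(spec, 1), 0.1)
  # stopband attenuation >= 20 dB below 2 Hz and above 40 Hz (design check)
  expect_lt(fir_gain(spec, 2), 10^(-20 / 20))
  expect_lt(fir_gain(spec, 40), 10^(-20 / 20))
  # passband within +-1 dB over 8-25 Hz
  for (f in seq(8, 25, by = 1))
    expect_true(abs(20 * log10(fir_gain(spec, f))) <= 1)
  # all-zero input stays zero
  z <- new_recording(matrix(0, 256 * 5, 6), 256, eeg_channels(), "EEG")
  expect_equal(bandpass(z, spec)$samples, z$samples, ignore_attr = TRUE)
})

test_that("measured response matches the design at probe frequencies", {
  spec <- filter_spec()
  for (f in c(1, 4, 10, 20, 30, 40)) {
    expect_equal(measured_gain(spec, f), fir_gain(spec, f),
                 tolerance = 0.02, label = paste("gain at", f, "Hz"))
  }
})

test_that("the filter is linear", {
  spec <- filter_spec()
  set.seed(1)
  x <- new_recording(matrix(rnorm(256 * 10), ncol = 1), 256, "AF3", "EEG")
  y <- new_recording(matrix(rnorm(256 * 10), ncol = 1), 256, "AF3", "EEG")
  lhs <- bandpass(new_recording(2 * x$samples + 3 * y$samples, 256, "AF3", "EEG"),
                  spec)$samples
  rhs <- 2 * bandpass(x, spec)$samples + 3 * bandpass(y, spec)$samples
  expect_equal(lhs, rhs, tolerance = 1e-9)
})

test_that("group delay is compensated", {
  # a pulse at sample k comes out centred at sample k, not k + order/2
  spec <- filter_spec()
  x <- numeric(256 * 4)
  x[256 * 2] <- 1
  rec <- new_recording(matrix(x, ncol = 1), 256, "AF3", "EEG")
  y <- bandpass(rec, spec)$samples[, 1]
  expect_equal(which.max(abs(y)), 256 * 2)
})

test_that("filter contract errors", {
  expect_error(filter_spec(order = 423), "even")
  spec <- filter_spec()
  wrong_fs <- new_recording(matrix(rnorm(512), ncol = 1), 512, "AF3", "EEG")
  expect_error(bandpass(wrong_fs, spec), "designed for")
  short <- new_recording(matrix(rnorm(100), ncol = 1), 256, "AF3", "EEG")
  expect_error(bandpass(short, spec), "order")
})
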