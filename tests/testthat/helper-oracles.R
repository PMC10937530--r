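# Independent oracles used across tests: deliberately naive re-derivations
# that share no code with the implementation they check.

# three-back correctness by literal enumeration over a response log
oracle_three_back <- function(digit, response) {
  n <- length(digit)
  correct <- rep(NA, n)
  for (i in seq_len(n)) {
    if (i <= 3) next
    truth <- if (digit[i] == digit[i - 3]) "match" else "nonmatch"
    if (response[i] %in% c("match", "nonmatch"))
      correct[i] <- response[i] == truth
  }
  correct
}

# Benjamini-Hochberg by the step-up definition, one comparison at a time
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running_min <- Inf
  for (k in m:1) {
    running_min <- min(running_min, p[o[k]] * m / k)
    adj[o[k]] <- min(running_min, 1)
  }
  adj
}

# frequency of the largest FFT magnitude of a demeaned series (fs in Hz)
oracle_peak_freq <- function(x, fs) {
  x <- x - mean(x)
  n <- length(x)
  mag <- Mod(fft(x))[2:floor(n / 2)]
  which.max(mag) * fs / n
}

# RMSSD of sinusoidally modulated intervals, closed form:
# intervals T[k] = mean + a*sin(2*pi*f*mean_s*k)  ->  a*sqrt(2)*|sin(pi*f*mean_s)|
oracle_rmssd_sin <- function(a_ms, f_hz, mean_ibi_s) {
  a_ms * sqrt(2) * abs(sin(pi * f_hz * mean_ibi_s))
}

# unit sinusoid EEG recording on the standard montage
sine_eeg <- function(freq_hz, duration_s = 300, fs = 256, amp = 1,
                     n_channels = 6) {
  t <- (seq_len(duration_s * fs) - 1) / fs
  new_recording(matrix(rep(amp * sin(2 * pi * freq_hz * t), n_channels),
                       ncol = n_channels),
                fs = fs, channel_labels = eeg_channels()[1:n_channels],
                modality = "EEG")
}

# single-channel power series helper
series_1ch <- function(x, fs_series = 1) {
  cogload:::new_power_series(matrix(x, ncol = 1), band_def("alpha"),
                             fs_series = fs_series, t0_s = 0,
                             channel_labels = "AF3")
}

series_6ch <- function(X) {
  cogload:::new_power_series(X, band_def("alpha"), fs_series = 1, t0_s = 0,
                             channel_labels = eeg_channels())
}
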