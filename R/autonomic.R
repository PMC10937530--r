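#' Detect pulse peaks in a PPG recording
#'
#' Noise-reduced peak detection validated by autocorrelation: the signal is
#' band-limited to the pulse band (0.5-8 Hz, zero-phase Butterworth), the
#' beat period is estimated from the autocorrelation of 10-s windows, and
#' candidate local maxima are gated against a running period estimate —
#' peaks closer than `gate[1]`x or farther than `gate[2]`x the running period
#' are rejected. A signal with no detectable periodicity in the plausible
#' beat range is an error, not an empty result.
#'
#' @param ppg single-channel PPG recording (protocol rate 512 Hz), >= 30 s.
#' @param band pulse band edges in Hz for the noise-reduction filter.
#' @param acf_window_s autocorrelation window for period estimation.
#' @param gate lower/upper multiples of the running period accepted between
#'   successive beats.
#' @return A `beat_series`: `beat_times_s` (seconds, recording time axis) and
#'   `nn_intervals_ms` (successive differences, artifact-screened by
#'   [screen_nn()]).
#' @export
detect_pulses <- function(ppg, band = c(0.5, 8), acf_window_s = 10,
                          gate = c(0.5, 1.5)) {
  validate_recording(ppg, modality = "PPG", n_channels = 1)
  fs <- ppg$fs
  x <- as.numeric(ppg$samples[, 1])
  if (length(x) / fs < 30) stop("need at least 30 s of PPG")
  if (sd(x) < .Machine$double.eps * max(1, abs(mean(x))))
    stop("no pulse periodicity detectable in the PPG signal (flat input)")
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  y <- as.numeric(signal::filtfilt(bf, x))

  # global beat-period estimate from the autocorrelation of 10-s windows
  lag_rng <- round(c(0.3, 2.0) * fs)           # 30-200 bpm
  n_win <- max(1L, floor(length(y) / (acf_window_s * fs)))
  periods <- vapply(seq_len(n_win), function(w) {
    seg <- y[((w - 1) * acf_window_s * fs + 1):min(w * acf_window_s * fs, length(y))]
    a <- stats::acf(seg, lag.max = lag_rng[2], plot = FALSE)$acf
    lag_best <- which.max(a[(lag_rng[1] + 1):(lag_rng[2] + 1)]) + lag_rng[1] - 1L
    if (max(a[(lag_rng[1] + 1):(lag_rng[2] + 1)]) < 0.2) NA_real_
    else lag_best / fs
  }, numeric(1))
  if (all(is.na(periods)))
    stop("no pulse periodicity detectable in the PPG signal")
  period0 <- median(periods, na.rm = TRUE)

  # candidate peaks: local maxima above an amplitude floor
  d <- diff(y)
  cand <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  cand <- cand[y[cand] > 0.3 * stats::quantile(y[cand], 0.75)]
  if (length(cand) < 2) stop("no pulse peaks found")

  # gate candidates against the running period
  keep <- cand[1]
  period <- period0
  for (p in cand[-1]) {
    gap <- (p - keep[length(keep)]) / fs
    if (gap < gate[1] * period) {
      # too close: keep the larger of the two
      if (y[p] > y[keep[length(keep)]]) keep[length(keep)] <- p
    } else if (gap > gate[2] * period) {
      keep <- c(keep, p)                       # gap too long: accept and resync
    } else {
      keep <- c(keep, p)
      period <- 0.8 * period + 0.2 * gap       # running update
    }
  }
  beat_times <- (keep - 1) / fs + ppg$start_time
  nn <- screen_nn(diff(beat_times) * 1000)
  structure(list(beat_times_s = beat_times, nn_intervals_ms = nn),
            class = "beat_series")
}

#' Artifact-screen a sequence of inter-beat intervals
#'
#' Drops intervals outside the physiological range and intervals deviating
#' from the local (11-beat) median by more than `rel_tol`, the usual
#' pre-RMSSD screening for ectopy and missed/spurious detections.
#'
#' @param nn_ms inter-beat intervals in milliseconds.
#' @param range_ms acceptable absolute range (default 300-2000 ms).
#' @param rel_tol maximum relative deviation from the running median.
#' @return Screened intervals (shorter than the input if any were dropped).
#' @export
screen_nn <- function(nn_ms, range_ms = c(300, 2000), rel_tol = 0.25) {
  ok <- nn_ms >= range_ms[1] & nn_ms <= range_ms[2]
  if (length(nn_ms) >= 3) {
    loc_med <- stats::runmed(nn_ms, k = min(11L, 2L * (length(nn_ms) %/% 2L) - 1L))
    ok <- ok & abs(nn_ms - loc_med) <= rel_tol * loc_med
  }
  nn_ms[ok]
}

#' Root mean square of successive differences
#'
#' The time-domain HRV index used throughout: `sqrt(mean(diff(nn)^2))`,
#' reflecting beat-to-beat (parasympathetically mediated) variability.
#'
#' @param nn_intervals_ms inter-beat intervals in milliseconds (>= 2), or a
#'   `beat_series` from [detect_pulses()].
#' @return RMSSD in milliseconds.
#' @export
rmssd <- function(nn_intervals_ms) {
  if (inherits(nn_intervals_ms, "beat_series"))
    nn_intervals_ms <- nn_intervals_ms$nn_intervals_ms
  if (length(nn_intervals_ms) < 2)
    stop("need at least 2 inter-beat intervals")
  sqrt(mean(diff(nn_intervals_ms)^2))
}

#' Detect skin conductance responses
#'
#' Trough-to-peak SCR detection: the EDA signal is low-pass smoothed and
#' downsampled, local minima are paired with the following local maximum, and
#' deflections with rise time inside `rise_range_s` and amplitude at or above
#' `min_amplitude_uS` are counted as SCR events.
#'
#' @param eda single-channel EDA recording (protocol rate 512 Hz), >= 60 s.
#' @param min_amplitude_uS detection threshold in microsiemens (default 0.05,
#'   the common convention).
#' @param rise_range_s acceptable trough-to-peak rise time in seconds.
#' @return An `scr_events` object: `onset_times_s`, `amplitudes_uS`,
#'   `rate_per_min`.
#' @export
detect_scr <- function(eda, min_amplitude_uS = 0.05, rise_range_s = c(1, 5)) {
  validate_recording(eda, modality = "EDA", n_channels = 1)
  dur <- duration(eda)
  if (dur < 60) stop("need at least 60 s of EDA")
  fs <- eda$fs
  # smooth to the phasic timescale and decimate to 16 Hz for peak picking
  fs_ds <- 16
  dec <- round(fs / fs_ds)
  bf <- signal::butter(2, 2 / (fs / 2), type = "low")
  y <- as.numeric(signal::filtfilt(bf, as.numeric(eda$samples[, 1])))
  y <- y[seq(1, length(y), by = dec)]

  d <- diff(y)
  maxima <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  minima <- which(d[-length(d)] < 0 & d[-1] >= 0) + 1L
  if (length(y) > 1 && d[1] > 0) minima <- c(1L, minima)
  onsets <- numeric(0); amps <- numeric(0)
  for (m in maxima) {
    tr <- minima[minima < m]
    if (!length(tr)) next
    tr <- tr[length(tr)]
    rise <- (m - tr) / fs_ds
    amp <- y[m] - y[tr]
    if (rise >= rise_range_s[1] && rise <= rise_range_s[2] &&
        amp >= min_amplitude_uS) {
      onsets <- c(onsets, (tr - 1) / fs_ds + eda$start_time)
      amps <- c(amps, amp)
    }
  }
  structure(list(onset_times_s = onsets, amplitudes_uS = amps,
                 rate_per_min = length(onsets) / (dur / 60)),
            class = "scr_events")
}
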