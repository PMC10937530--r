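#' EEG band-limiting filter specification
#'
#' Linear-phase FIR bandpass used on every EEG channel before spectral feature
#' extraction. The reference design is a 4-30 Hz passband of order 424 at
#' 256 Hz; the even order makes the group delay an integer (order/2 samples),
#' which [bandpass()] compensates exactly.
#'
#' @param low_hz,high_hz passband edges in Hz.
#' @param order FIR order (even).
#' @param fs design sampling rate in Hz.
#' @return An object of class `filter_spec` holding the designed coefficients.
#' @export
filter_spec <- function(low_hz = 4, high_hz = 30, order = 424, fs = 256) {
  stopifnot(low_hz > 0, low_hz < high_hz, high_hz < fs / 2)
  if (order %% 2 != 0) stop("FIR order must be even for integer group delay")
  h <- signal::fir1(order, c(low_hz, high_hz) / (fs / 2), type = "pass",
                    window = signal::hamming(order + 1))
  structure(list(low_hz = low_hz, high_hz = high_hz, order = order, fs = fs,
                 coef = as.numeric(h)),
            class = "filter_spec")
}

#' Remove per-channel DC offset
#'
#' Subtracts each channel's sample mean, the first preprocessing step before
#' band-limiting.
#'
#' @param recording a [new_recording()] object.
#' @return The recording with zero-mean channels.
#' @export
remove_offset <- function(recording) {
  stopifnot(inherits(recording, "cog_recording"))
  if (nrow(recording$samples) == 0L) stop("empty recording")
  recording$samples <- sweep(recording$samples, 2,
                             colMeans(recording$samples))
  recording
}

#' Bandpass-filter an EEG recording
#'
#' Applies the linear-phase FIR filter per channel by direct convolution and
#' shifts the output by the order/2-sample group delay, so filtered samples
#' stay aligned with the input time axis. Output length equals input length;
#' the first and last order/2 samples carry edge transients (under a second at
#' the default order) and downstream 20-s windows make them negligible.
#'
#' @param recording a zero-mean EEG recording at the spec's design rate.
#' @param spec a [filter_spec()].
#' @return The filtered recording.
#' @export
bandpass <- function(recording, spec = filter_spec()) {
  stopifnot(inherits(recording, "cog_recording"), inherits(spec, "filter_spec"))
  if (recording$fs != spec$fs)
    stop("recording is at ", recording$fs, " Hz but the filter was designed for ",
         spec$fs, " Hz")
  n <- nrow(recording$samples)
  if (spec$order >= n)
    stop("filter order (", spec$order, ") >= signal length (", n, ")")
  half <- spec$order / 2
  # FFT convolution at an FFT-friendly length, group delay removed
  N <- stats::nextn(n + spec$order, c(2, 3, 5))
  H <- fft(c(spec$coef, numeric(N - spec$order - 1)))
  recording$samples <- apply(recording$samples, 2, function(x) {
    y <- Re(fft(fft(c(x, numeric(N - n))) * H, inverse = TRUE)) / N
    y[(half + 1):(half + n)]
  })
  recording
}
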