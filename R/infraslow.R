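#' Period band for infra-slow fluctuation analysis
#'
#' Bands are stated as periods (seconds) because the phenomena of interest
#' are slow: the index numerator is 64-128 s, its denominator 5-128 s, and
#' the second-order feature band 40-90 s. The corresponding frequency band is
#' `[1/long_s, 1/short_s]` Hz.
#'
#' @param short_s,long_s period bounds in seconds, `short_s < long_s`.
#' @return A `period_band` object.
#' @export
period_band <- function(short_s, long_s) {
  stopifnot(short_s > 0, short_s < long_s)
  structure(list(short_s = short_s, long_s = long_s,
                 low_hz = 1 / long_s, high_hz = 1 / short_s),
            class = "period_band")
}

#' Fluctuation spectrum of a band-power time series
#'
#' Welch PSD of one channel of a first-order power series: Hann-tapered
#' segments of `seg_len` samples (default 256, the shortest length resolving
#' two cycles of a 128-s period at the 1-Hz series rate), 50% overlap,
#' linear detrending per segment, zero-padded to twice the segment length so
#' the frequency grid is finer than 1/256 Hz. Detrending removes the mean
#' level and slow drift, so the spectrum describes fluctuations only.
#'
#' @param x numeric vector, one channel of a power series.
#' @param fs_series series sampling rate in Hz (1 for the protocol's 1-s shift).
#' @param seg_len Welch segment length in samples.
#' @param detrend `"linear"` (default) or `"none"`.
#' @return List with `freq` (Hz) and `psd`.
#' @export
fluctuation_spectrum <- function(x, fs_series = 1, seg_len = 256,
                                 detrend = c("linear", "none")) {
  if (length(x) < seg_len)
    stop("power series too short (", length(x), " samples) to resolve the ",
         "longest analysis period; need >= ", seg_len)
  welch_psd(x, fs = fs_series, seg_len = seg_len, overlap = 0.5,
            window = "hann", detrend = match.arg(detrend),
            nfft = 2L * seg_len)
}

#' Infra-slow fluctuation index of alpha power
#'
#' The headline EEG feature: per channel, the fluctuation power of the alpha
#' band-power series in the 64-128 s period band divided by that in the
#' 5-128 s band, then averaged over channels. Because the numerator band is
#' nested in the denominator band the index lies in `[0, 1]`; a series with
#' all of its rhythmic energy at a ~100-s period scores near 1, white noise
#' scores near the bandwidth ratio
#' (1/64 - 1/128) / (1/5 - 1/128) = 0.0407.
#'
#' @param alpha_series a `power_series` (per-channel alpha fractions at 1 Hz).
#' @param num_band index numerator, a [period_band()] (default 64-128 s).
#' @param den_band index denominator (default 5-128 s).
#' @param condition optional task label carried through to reports.
#' @inheritParams fluctuation_spectrum
#' @return An `infraslow_index` object: `value` (channel mean), `per_channel`,
#'   `condition`.
#' @export
infraslow_index <- function(alpha_series,
                            num_band = period_band(64, 128),
                            den_band = period_band(5, 128),
                            condition = NULL, seg_len = 256,
                            detrend = c("linear", "none")) {
  stopifnot(inherits(alpha_series, "power_series"))
  detrend <- match.arg(detrend)
  n <- nrow(alpha_series$values)
  if (n < 2 * num_band$long_s * alpha_series$fs_series)
    warning("power series (", n / alpha_series$fs_series,
            " s) holds fewer than 2 cycles of the longest period (",
            num_band$long_s, " s); the index estimate will be noisy")
  per_channel <- apply(alpha_series$values, 2, function(x) {
    if (anyNA(x)) x <- approx(seq_along(x), x, seq_along(x), rule = 2)$y
    ps <- fluctuation_spectrum(x, alpha_series$fs_series, seg_len, detrend)
    den <- band_power(ps$freq, ps$psd, den_band$low_hz, den_band$high_hz)
    if (den <= 0) stop("zero fluctuation power in the denominator band")
    band_power(ps$freq, ps$psd, num_band$low_hz, num_band$high_hz) / den
  })
  structure(list(value = mean(per_channel), per_channel = per_channel,
                 condition = condition),
            class = "infraslow_index")
}

#' @export
print.infraslow_index <- function(x, ...) {
  cat(sprintf("<infraslow_index>%s value = %.4f\n",
              if (is.null(x$condition)) "" else paste0(" [", x$condition, "]"),
              x$value))
  cat("  per channel:",
      paste(sprintf("%s=%.3f", names(x$per_channel), x$per_channel),
            collapse = " "), "\n")
  invisible(x)
}

# Sliding in-band fluctuation power of one 1-Hz series: windows of `win`
# samples shifted by `shift`, each linearly detrended, Hann tapered,
# zero-padded to the next power of two, integrated over [flo, fhi] Hz.
sliding_fluct_power <- function(x, win, shift, flo, fhi, fs_series = 1) {
  n <- length(x)
  n_win <- floor((n - win) / shift) + 1L
  starts <- (seq_len(n_win) - 1L) * shift + 1L
  idx <- outer(seq_len(win) - 1L, starts, "+")
  segs <- matrix(x[idx], nrow = win)
  # project out per-column mean and linear trend (fixed design, vectorized)
  D <- cbind(1, seq_len(win))
  segs <- segs - D %*% solve(crossprod(D), crossprod(D, segs))
  w <- taper_window(win, "hann")
  nfft <- 2^ceiling(log2(2 * win))
  padded <- rbind(segs * w, matrix(0, nfft - win, n_win))
  n_freq <- nfft / 2 + 1L
  dbl <- rep(2, n_freq); dbl[c(1, n_freq)] <- 1
  P <- (Mod(stats::mvfft(padded))^2 / (fs_series * sum(w^2)))[seq_len(n_freq), , drop = FALSE] * dbl
  freq <- (seq_len(n_freq) - 1L) * fs_series / nfft
  apply(P, 2, function(p) band_power(freq, p, flo, fhi))
}

#' Second-order band-power fluctuation series
#'
#' Sliding-window fluctuation power of a first-order band-power series:
#' 130-s windows advanced by 1 s, each reduced to the integrated fluctuation
#' power in the 40-90 s period band. This is the temporally-longer feature
#' feeding the arousal model; a first-order series of length L yields
#' L - 130 + 1 values per channel.
#'
#' @param band_series a `power_series` (alpha or theta first-order series).
#' @param window_s window length in seconds (default 130).
#' @param shift_s window shift in seconds (default 1).
#' @param band [period_band()] to integrate (default 40-90 s).
#' @return A `power_series` of in-band fluctuation power. Values are stamped
#'   at their window start; consumers that need causal alignment should use
#'   the trailing (window-end) convention, see [build_features()].
#' @export
second_order_series <- function(band_series, window_s = 130, shift_s = 1,
                                band = period_band(40, 90)) {
  stopifnot(inherits(band_series, "power_series"))
  fs <- band_series$fs_series
  win <- round(window_s * fs)
  shift <- round(shift_s * fs)
  if (nrow(band_series$values) < win)
    stop("first-order series (", nrow(band_series$values),
         " samples) shorter than the second-order window (", win, ")")
  vals <- apply(band_series$values, 2, sliding_fluct_power,
                win = win, shift = shift,
                flo = band$low_hz, fhi = band$high_hz, fs_series = fs)
  if (is.vector(vals)) vals <- matrix(vals, nrow = 1)
  new_power_series(vals, band = band_series$band, fs_series = fs,
                   t0_s = band_series$t0_s,
                   channel_labels = colnames(band_series$values))
}
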