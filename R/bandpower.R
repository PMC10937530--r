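#' EEG frequency band definitions
#'
#' Protocol bands: alpha 8-13 Hz, theta 4-7 Hz, both normalized by the total
#' 4-30 Hz band.
#'
#' @param name `"alpha"`, `"theta"` or `"total"`, or pass explicit edges.
#' @param low_hz,high_hz explicit band edges (override the named defaults).
#' @return A list with `name`, `low_hz`, `high_hz` of class `band_def`.
#' @export
band_def <- function(name = c("alpha", "theta", "total"),
                     low_hz = NULL, high_hz = NULL) {
  name <- match.arg(name)
  edges <- switch(name, alpha = c(8, 13), theta = c(4, 7), total = c(4, 30))
  if (!is.null(low_hz)) edges[1] <- low_hz
  if (!is.null(high_hz)) edges[2] <- high_hz
  stopifnot(edges[1] < edges[2])
  structure(list(name = name, low_hz = edges[1], high_hz = edges[2]),
            class = "band_def")
}

#' Sliding-window Welch spectra of an EEG recording
#'
#' Welch PSD (non-overlapping `segment_s`-second Hann-tapered segments) on
#' `window_s`-second windows advanced by `shift_s`, per channel. With the
#' protocol parameters (20-s windows, 1-s shift, 1-s segments) the frequency
#' resolution is 1 Hz and a 300-s recording yields 281 windows.
#'
#' @param recording preprocessed EEG, a [new_recording()] object.
#' @param window_s window length in seconds (default 20).
#' @param shift_s window shift in seconds (default 1).
#' @param segment_s Welch segment length in seconds (default 1).
#' @param window taper, `"hann"` (default) or `"rect"`.
#' @return List with `freq` (Hz), `spectra` (array window x frequency x
#'   channel), `t0_s` (time of the first window's start) and `shift_s`.
#' @export
sliding_psd <- function(recording, window_s = 20, shift_s = 1, segment_s = 1,
                        window = c("hann", "rect")) {
  window <- match.arg(window)
  stopifnot(inherits(recording, "cog_recording"))
  fs <- recording$fs
  dur <- duration(recording)
  if (dur < window_s)
    stop("recording (", dur, " s) shorter than the analysis window (",
         window_s, " s)")
  seg_n <- round(fs * segment_s)
  if (abs(seg_n - fs * segment_s) > 1e-9)
    stop("fs * segment_s must be an integer number of samples")
  if (abs(window_s / segment_s - round(window_s / segment_s)) > 1e-9)
    stop("window_s must be a multiple of segment_s")
  n_per_win <- round(window_s / segment_s)
  n_win <- floor((dur - window_s) / shift_s) + 1L
  win_starts_s <- (seq_len(n_win) - 1L) * shift_s
  seg_starts_s <- sort(unique(as.vector(outer(
    win_starts_s, (seq_len(n_per_win) - 1L) * segment_s, "+"))))
  seg_starts <- round(seg_starts_s * fs) + 1L

  w <- taper_window(seg_n, window)
  u <- sum(w^2)
  n_freq <- floor(seg_n / 2) + 1L
  dbl <- rep(2, n_freq); dbl[1] <- 1
  if (seg_n %% 2 == 0) dbl[n_freq] <- 1

  # membership matrix: segment i contributes to window j
  memb <- outer(seg_starts_s, win_starts_s, function(s, ws)
    s >= ws - 1e-9 & s <= ws + window_s - segment_s + 1e-9) * 1
  n_ch <- ncol(recording$samples)
  spectra <- array(NA_real_, dim = c(n_win, n_freq, n_ch))
  idx <- outer(seq_len(seg_n) - 1L, seg_starts, "+")
  for (ch in seq_len(n_ch)) {
    segs <- matrix(recording$samples[idx, ch], nrow = seg_n) * w
    P <- (Mod(stats::mvfft(segs))^2 / (fs * u))[seq_len(n_freq), , drop = FALSE] * dbl
    spectra[, , ch] <- t(P %*% memb) / colSums(memb)
  }
  list(freq = (seq_len(n_freq) - 1L) / segment_s, spectra = spectra,
       t0_s = recording$start_time, shift_s = shift_s,
       channel_labels = recording$channel_labels)
}

#' Fraction of spectral power in a band
#'
#' Integrated PSD over `band` divided by the integral over `total`
#' (trapezoidal rule, [band_power()]); a flat spectrum therefore yields the
#' bandwidth ratio, e.g. alpha/total = (13-8)/(30-4) = 0.1923.
#'
#' @param freq frequency grid in Hz.
#' @param psd PSD values.
#' @param band,total [band_def()] objects; `band` must nest inside `total`.
#' @return Fraction in `[0, 1]`; `NA` when the total band has zero power.
#' @export
band_fraction <- function(freq, psd, band = band_def("alpha"),
                          total = band_def("total")) {
  stopifnot(band$low_hz >= total$low_hz, band$high_hz <= total$high_hz)
  denom <- band_power(freq, psd, total$low_hz, total$high_hz)
  if (denom <= 0) return(NA_real_)
  band_power(freq, psd, band$low_hz, band$high_hz) / denom
}

#' First-order band-power time series
#'
#' The per-second sequence of normalized band power: sliding-window Welch
#' spectra ([sliding_psd()]) reduced to a band fraction ([band_fraction()])
#' per window and channel. Each value is stamped at its window's start time.
#'
#' @param recording preprocessed EEG.
#' @param band [band_def()] to normalize (alpha or theta).
#' @param total normalization band (default 4-30 Hz).
#' @inheritParams sliding_psd
#' @return A `power_series` object: `values` (matrix window x channel),
#'   `band`, `fs_series` (Hz, = 1/`shift_s`), `t0_s`.
#' @export
first_order_series <- function(recording, band = band_def("alpha"),
                               total = band_def("total"),
                               window_s = 20, shift_s = 1, segment_s = 1,
                               window = c("hann", "rect")) {
  sp <- sliding_psd(recording, window_s, shift_s, segment_s, match.arg(window))
  band_fraction_series(sp, band, total)
}

#' Reduce sliding spectra to a band-fraction series
#'
#' Converts a [sliding_psd()] result into a `power_series` of
#' [band_fraction()] values, one per window and channel. Splitting this from
#' [first_order_series()] lets one sliding-spectra computation serve several
#' bands. Zero-total-power windows become `NA`.
#'
#' @param sp a [sliding_psd()] result.
#' @param band,total [band_def()] objects.
#' @return A `power_series`.
#' @export
band_fraction_series <- function(sp, band = band_def("alpha"),
                                 total = band_def("total")) {
  stopifnot(band$low_hz >= total$low_hz, band$high_hz <= total$high_hz)
  # band_power is linear in the PSD: precompute its weight vector once
  wts <- function(lo, hi) vapply(seq_along(sp$freq), function(j) {
    e <- numeric(length(sp$freq)); e[j] <- 1
    band_power(sp$freq, e, lo, hi)
  }, numeric(1))
  w_band <- wts(band$low_hz, band$high_hz)
  w_tot <- wts(total$low_hz, total$high_hz)
  n_ch <- dim(sp$spectra)[3]
  vals <- vapply(seq_len(n_ch), function(ch) {
    S <- sp$spectra[, , ch, drop = TRUE]
    num <- as.vector(S %*% w_band)
    den <- as.vector(S %*% w_tot)
    ifelse(den > 0, num / den, NA_real_)
  }, numeric(dim(sp$spectra)[1]))
  if (is.vector(vals)) vals <- matrix(vals, nrow = 1)
  new_power_series(vals, band = band, fs_series = 1 / sp$shift_s,
                   t0_s = sp$t0_s, channel_labels = sp$channel_labels)
}

new_power_series <- function(values, band, fs_series, t0_s,
                             channel_labels = NULL) {
  if (is.vector(values)) values <- matrix(values, ncol = 1)
  if (!is.null(channel_labels)) colnames(values) <- channel_labels
  structure(list(values = values, band = band, fs_series = fs_series,
                 t0_s = t0_s),
            class = "power_series")
}

#' @export
print.power_series <- function(x, ...) {
  cat(sprintf("<power_series> %s: %d samples x %d channel(s) @ %g Hz (t0 = %g s)\n",
              x$band$name, nrow(x$values), ncol(x$values), x$fs_series, x$t0_s))
  invisible(x)
}
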