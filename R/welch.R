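# Welch spectral estimation and band integration. These primitives sit under
# every feature in the package (band power, infra-slow index, RT spectrum),
# so they are written once here with an explicit, testable contract.

taper_window <- function(n, type = c("hann", "rect")) {
  type <- match.arg(type)
  if (type == "rect") return(rep(1, n))
  # periodic Hann, the usual choice for averaged periodograms
  0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / n)
}

linear_detrend <- function(x) {
  n <- length(x)
  t <- seq_len(n)
  x - (lm.fit(cbind(1, t), x)$fitted.values)
}

#' Welch power spectral density estimate
#'
#' Splits the signal into `seg_len`-sample segments (optionally overlapping),
#' tapers each, and averages the one-sided periodograms. The PSD is scaled so
#' that `sum(psd) * df` equals the signal variance for a rectangular taper
#' (density in units^2/Hz).
#'
#' @param x numeric vector.
#' @param fs sampling rate in Hz.
#' @param seg_len segment length in samples (default: whole signal, a single
#'   tapered periodogram).
#' @param overlap fraction of segment overlap in `[0, 1)` (default 0).
#' @param window `"hann"` (default) or `"rect"`.
#' @param detrend `"none"` or `"linear"` (per segment).
#' @param nfft FFT length, >= `seg_len`; zero-padding refines the frequency
#'   grid without adding information.
#' @return A list with `freq` (Hz, 0 to Nyquist) and `psd`.
#' @export
welch_psd <- function(x, fs, seg_len = length(x), overlap = 0,
                      window = c("hann", "rect"),
                      detrend = c("none", "linear"), nfft = NULL) {
  window <- match.arg(window)
  detrend <- match.arg(detrend)
  n <- length(x)
  if (seg_len > n) stop("seg_len (", seg_len, ") exceeds signal length (", n, ")")
  if (is.null(nfft)) nfft <- seg_len
  if (nfft < seg_len) stop("nfft must be >= seg_len")
  step <- max(1L, as.integer(round(seg_len * (1 - overlap))))
  starts <- seq(1L, n - seg_len + 1L, by = step)
  w <- taper_window(seg_len, window)
  u <- sum(w^2)                       # taper power normalization
  segs <- vapply(starts, function(s) {
    seg <- x[s:(s + seg_len - 1L)]
    if (detrend == "linear") seg <- linear_detrend(seg)
    c(seg * w, rep(0, nfft - seg_len))
  }, numeric(nfft))
  spec <- Mod(stats::mvfft(segs))^2 / (fs * u)
  n_keep <- floor(nfft / 2) + 1L
  psd <- rowMeans(spec)[seq_len(n_keep)]
  # one-sided: double everything except DC (and Nyquist when nfft is even)
  dbl <- rep(2, n_keep)
  dbl[1] <- 1
  if (nfft %% 2 == 0) dbl[n_keep] <- 1
  list(freq = (seq_len(n_keep) - 1L) * fs / nfft, psd = psd * dbl)
}

#' Integrate a power spectral density over a frequency band
#'
#' Trapezoidal integration of the PSD over `[low_hz, high_hz]`, with linear
#' interpolation at band edges that fall between grid points. With this rule a
#' flat spectrum integrates to `level * (high - low)` exactly, so band
#' fractions of flat spectra equal bandwidth ratios.
#'
#' @param freq frequency grid (Hz, ascending).
#' @param psd PSD values on `freq`.
#' @param low_hz,high_hz band edges in Hz.
#' @return Integrated band power (units^2).
#' @export
band_power <- function(freq, psd, low_hz, high_hz) {
  stopifnot(low_hz < high_hz)
  lo <- max(low_hz, freq[1])
  hi <- min(high_hz, freq[length(freq)])
  if (hi <= lo) return(0)
  inside <- freq > lo & freq < hi
  f_grid <- c(lo, freq[inside], hi)
  p_grid <- approx(freq, psd, xout = f_grid, rule = 2)$y
  sum(diff(f_grid) * (head(p_grid, -1) + tail(p_grid, -1)) / 2)
}
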