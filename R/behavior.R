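#' Score a three-back run
#'
#' For trial i (1-based, i >= 4) the correct answer is `"match"` when the
#' current digit equals the digit three trials earlier and `"nonmatch"`
#' otherwise; the first three trials have no defined answer and are flagged
#' non-scorable.
#'
#' @param run a [new_task_run()] object (or its `trials` data.frame).
#' @return The trials data.frame with added columns `truth`, `scorable` and
#'   `correct` (NA for non-scorable or omitted trials).
#' @export
score_three_back <- function(run) {
  trials <- if (inherits(run, "task_run")) run$trials else run
  n <- nrow(trials)
  if (n < 4) stop("three-back needs at least 4 trials to score anything")
  bad <- setdiff(unique(trials$response), c("match", "nonmatch", "none", NA))
  if (length(bad))
    stop("malformed three-back responses: ", paste(bad, collapse = ", "))
  truth <- rep(NA_character_, n)
  idx <- 4:n
  truth[idx] <- ifelse(trials$digit[idx] == trials$digit[idx - 3L],
                       "match", "nonmatch")
  trials$truth <- truth
  trials$scorable <- !is.na(truth)
  trials$correct <- ifelse(trials$scorable & trials$response %in% c("match", "nonmatch"),
                           trials$response == truth, NA)
  trials
}

#' Score a zero-back (parity judgment) run
#'
#' The correct answer is `"even"` or `"odd"` according to the parity of the
#' presented digit; every trial is scorable.
#'
#' @inheritParams score_three_back
#' @return The trials data.frame with added `truth`, `scorable`, `correct`.
#' @export
score_zero_back <- function(run) {
  trials <- if (inherits(run, "task_run")) run$trials else run
  if (nrow(trials) < 1) stop("no trials to score")
  bad <- setdiff(unique(trials$response), c("even", "odd", "none", NA))
  if (length(bad))
    stop("malformed zero-back responses: ", paste(bad, collapse = ", "))
  trials$truth <- ifelse(trials$digit %% 2 == 0, "even", "odd")
  trials$scorable <- TRUE
  trials$correct <- ifelse(trials$response %in% c("even", "odd"),
                           trials$response == trials$truth, NA)
  trials
}

score_run <- function(run) {
  if (run$condition == "three_back") score_three_back(run)
  else score_zero_back(run)
}

#' Accuracy of a scored run
#'
#' Fraction correct among scorable trials. By default omitted responses count
#' as errors (every stimulus demanded an answer); set
#' `omissions = "exclude"` to drop them from the denominator instead.
#'
#' @param scored output of [score_three_back()] or [score_zero_back()].
#' @param omissions `"incorrect"` (default) or `"exclude"`.
#' @return Fraction in `[0, 1]`.
#' @export
accuracy <- function(scored, omissions = c("incorrect", "exclude")) {
  omissions <- match.arg(omissions)
  s <- scored[scored$scorable, ]
  if (omissions == "exclude") s <- s[!is.na(s$correct), ]
  if (nrow(s) == 0) return(NA_real_)
  sum(s$correct, na.rm = TRUE) / nrow(s)
}

#' Reaction-time indices of a run
#'
#' Mean RT over all responded trials (correct and incorrect alike) and the
#' interquartile range of the same set, using linear-interpolation (type-7)
#' quantiles — the IQR value depends on the quantile rule, so it is fixed
#' and documented here. Omitted trials are excluded and counted.
#'
#' @param run a [new_task_run()] object or a trials data.frame.
#' @param min_n minimum number of responded trials required.
#' @return List with `mean_rt_ms`, `rt_iqr_ms`, `n_responded`, `n_omitted`.
#' @export
rt_indices <- function(run, min_n = 8) {
  trials <- if (inherits(run, "task_run")) run$trials else run
  rt <- trials$rt_ms[!is.na(trials$rt_ms) & trials$response != "none"]
  if (length(rt) < min_n)
    stop("only ", length(rt), " responded trials; need >= ", min_n)
  q <- quantile(rt, c(0.25, 0.75), type = 7, names = FALSE)
  list(mean_rt_ms = mean(rt), rt_iqr_ms = q[2] - q[1],
       n_responded = length(rt), n_omitted = nrow(trials) - length(rt))
}

#' Low-frequency fluctuation spectrum of the reaction-time series
#'
#' Treats the per-trial RTs as a time series sampled once per
#' inter-stimulus interval (1/3 Hz at the protocol's 3-s ISI), linearly
#' interpolates missing responses, and computes a Welch PSD (Hann taper,
#' linear detrend). The scalar summary `rt_fluct_index` is the mean PSD over
#' the very-low-frequency band `0 < f < band_hz` (default 0.05 Hz), the band
#' in which cognitive load expresses itself as RT instability.
#'
#' @param run a [new_task_run()] object or trials data.frame.
#' @param isi_s inter-stimulus interval in seconds.
#' @param band_hz upper edge of the summarized band (Hz).
#' @param max_missing maximum tolerated fraction of omitted responses.
#' @param seg_len Welch segment length in samples (default 128 trials,
#'   50% overlap).
#' @return List with `freq`, `psd`, `rt_fluct_index`.
#' @export
rt_fluctuation_spectrum <- function(run, isi_s = NULL, band_hz = 0.05,
                                    max_missing = 0.2, seg_len = 128) {
  trials <- if (inherits(run, "task_run")) run$trials else run
  if (is.null(isi_s)) isi_s <- if (inherits(run, "task_run")) run$isi_s else 3
  rt <- trials$rt_ms
  rt[trials$response == "none"] <- NA
  frac_missing <- mean(is.na(rt))
  if (frac_missing > max_missing)
    stop(sprintf("%.0f%% of responses missing (> %.0f%% tolerated)",
                 100 * frac_missing, 100 * max_missing))
  if (anyNA(rt))
    rt <- approx(seq_along(rt), rt, seq_along(rt), rule = 2)$y
  fs <- 1 / isi_s
  seg_len <- min(seg_len, length(rt))
  ps <- welch_psd(rt, fs = fs, seg_len = seg_len, overlap = 0.5,
                  window = "hann", detrend = "linear", nfft = 2L * seg_len)
  in_band <- ps$freq > 0 & ps$freq < band_hz
  list(freq = ps$freq, psd = ps$psd,
       rt_fluct_index = mean(ps$psd[in_band]))
}

#' Summarize one behavioral run
#'
#' Convenience wrapper combining scoring, [accuracy()], [rt_indices()] and
#' [rt_fluctuation_spectrum()] into the scalar indices used by the
#' statistics layer.
#'
#' @param run a [new_task_run()] object.
#' @param omissions see [accuracy()].
#' @return List with `condition`, `accuracy`, `mean_rt_ms`, `rt_iqr_ms`,
#'   `rt_fluct_index`, `n_responded`, `n_omitted`.
#' @export
summarize_behavior <- function(run, omissions = c("incorrect", "exclude")) {
  stopifnot(inherits(run, "task_run"))
  scored <- score_run(run)
  rti <- rt_indices(run)
  fl <- rt_fluctuation_spectrum(run)
  list(condition = run$condition,
       accuracy = accuracy(scored, match.arg(omissions)),
       mean_rt_ms = rti$mean_rt_ms, rt_iqr_ms = rti$rt_iqr_ms,
       rt_fluct_index = fl$rt_fluct_index,
       n_responded = rti$n_responded, n_omitted = rti$n_omitted)
}
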