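#' Multi-channel physiological recording
#'
#' Container for a uniformly sampled signal block (EEG, PPG or EDA): a numeric
#' matrix of samples (time in rows, channels in columns), a sampling rate, an
#' ordered channel-label vector, the modality, and the start time of the first
#' sample relative to task onset.
#'
#' EEG recordings are expected at 256 Hz on the six frontal channels
#' AF3, AF4, F3, F4, F7 and F8 (amplitudes in microvolts); PPG and EDA are
#' expected single-channel at 512 Hz in device units (microsiemens for EDA).
#'
#' @param samples numeric matrix, time x channel (a vector is treated as one
#'   channel).
#' @param fs sampling rate in Hz.
#' @param channel_labels character vector of channel names, one per column.
#' @param modality one of `"EEG"`, `"PPG"`, `"EDA"`.
#' @param start_time time of the first sample in seconds, 0 = task onset.
#' @return An object of class `cog_recording`.
#' @export
#' @examples
#' x <- new_recording(matrix(rnorm(512 * 6), ncol = 6), fs = 256,
#'                    channel_labels = eeg_channels(), modality = "EEG")
#' duration(x)
new_recording <- function(samples, fs, channel_labels = NULL,
                          modality = c("EEG", "PPG", "EDA"),
                          start_time = 0) {
  modality <- match.arg(modality)
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1)
  if (!is.matrix(samples) || !is.numeric(samples))
    stop("'samples' must be a numeric matrix (time x channel)")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("'fs' must be a single positive number")
  if (is.null(channel_labels))
    channel_labels <- paste0("ch", seq_len(ncol(samples)))
  if (length(channel_labels) != ncol(samples))
    stop("channel_labels length (", length(channel_labels),
         ") != number of channels (", ncol(samples), ")")
  colnames(samples) <- channel_labels
  structure(list(samples = samples, fs = fs,
                 channel_labels = as.character(channel_labels),
                 modality = modality, start_time = start_time),
            class = "cog_recording")
}

#' Standard frontal EEG montage used throughout the package
#'
#' @return Character vector of the six frontal channel labels, in the fixed
#'   order used for feature construction.
#' @export
eeg_channels <- function() c("AF3", "AF4", "F3", "F4", "F7", "F8")

#' @export
print.cog_recording <- function(x, ...) {
  cat(sprintf("<cog_recording> %s: %d channel(s) x %d samples @ %g Hz (%.1f s, t0 = %g s)\n",
              x$modality, ncol(x$samples), nrow(x$samples), x$fs,
              nrow(x$samples) / x$fs, x$start_time))
  cat("  channels:", paste(x$channel_labels, collapse = ", "), "\n")
  invisible(x)
}

#' Duration of a recording in seconds
#' @param recording a `cog_recording`.
#' @return Duration in seconds.
#' @export
duration <- function(recording) {
  stopifnot(inherits(recording, "cog_recording"))
  nrow(recording$samples) / recording$fs
}

validate_recording <- function(recording, modality = NULL, fs = NULL,
                               n_channels = NULL) {
  stopifnot(inherits(recording, "cog_recording"))
  if (!is.null(modality) && recording$modality != modality)
    stop("expected a ", modality, " recording, got ", recording$modality)
  if (!is.null(fs) && recording$fs != fs)
    stop("expected sampling rate ", fs, " Hz, got ", recording$fs, " Hz")
  if (!is.null(n_channels) && ncol(recording$samples) != n_channels)
    stop("expected ", n_channels, " channel(s), got ", ncol(recording$samples))
  invisible(recording)
}

#' One condition's n-back behavioral run
#'
#' @param trials data.frame with columns `trial_index`, `digit` (0-9),
#'   `onset_s`, `response` (`"match"`/`"nonmatch"` for three-back,
#'   `"even"`/`"odd"` for zero-back, `"none"` for omissions) and `rt_ms`
#'   (`NA` for omissions).
#' @param condition `"zero_back"` or `"three_back"`.
#' @param isi_s inter-stimulus interval in seconds (protocol value: 3).
#' @return An object of class `task_run`.
#' @export
new_task_run <- function(trials, condition = c("zero_back", "three_back"),
                         isi_s = 3) {
  condition <- match.arg(condition)
  need <- c("trial_index", "digit", "onset_s", "response", "rt_ms")
  if (!all(need %in% names(trials)))
    stop("trials must have columns: ", paste(need, collapse = ", "))
  if (any(diff(trials$onset_s) <= 0))
    stop("trial onsets must be strictly increasing")
  if (any(!is.na(trials$rt_ms) & trials$rt_ms < 0))
    stop("rt_ms must be >= 0 or NA")
  structure(list(trials = as.data.frame(trials), condition = condition,
                 isi_s = isi_s, n_trials = nrow(trials)),
            class = "task_run")
}

#' @export
print.task_run <- function(x, ...) {
  cat(sprintf("<task_run> %s: %d trials, ISI %g s\n",
              x$condition, x$n_trials, x$isi_s))
  invisible(x)
}
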