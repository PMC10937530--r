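#' Read a signal recording from CSV or EDF
#'
#' CSV files carry one column per channel with a single header row of channel
#' labels; time is implicit from the sampling rate. EDF files carry their own
#' header, which must agree with `fs_expected` — a mismatch is an error, never
#' a silent resample.
#'
#' @param path file to read (`.edf` is parsed as EDF, anything else as CSV).
#' @param modality `"EEG"`, `"PPG"` or `"EDA"`.
#' @param fs_expected declared sampling rate in Hz. Defaults to the protocol
#'   rates: 256 for EEG, 512 for PPG/EDA.
#' @param start_time start of the recording in seconds relative to task onset
#'   (CSV only; EDF stores its own).
#' @return A [new_recording()] object.
#' @export
read_recording <- function(path, modality = c("EEG", "PPG", "EDA"),
                           fs_expected = NULL, start_time = 0) {
  modality <- match.arg(modality)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(fs_expected))
    fs_expected <- if (modality == "EEG") 256 else 512
  if (grepl("\\.edf$", path, ignore.case = TRUE)) {
    rec <- read_edf(path)
    if (abs(rec$fs - fs_expected) > 1e-9)
      stop("EDF declares ", rec$fs, " Hz but fs_expected = ", fs_expected,
           " Hz; refusing to resample")
    rec$modality <- modality
  } else {
    dt <- data.table::fread(path, header = TRUE)
    if (ncol(dt) < 1L || nrow(dt) == 0L) stop("empty or unparseable CSV: ", path)
    if (!all(vapply(dt, is.numeric, TRUE)))
      stop("non-numeric column in ", path, "; expected headered numeric CSV")
    rec <- new_recording(as.matrix(dt), fs = fs_expected,
                         channel_labels = names(dt), modality = modality,
                         start_time = start_time)
  }
  n_expected <- if (modality == "EEG") 6L else 1L
  validate_recording(rec, modality = modality, n_channels = n_expected)
  if (modality == "EEG" && !all(rec$channel_labels %in% eeg_channels()))
    stop("EEG channel labels must be drawn from: ",
         paste(eeg_channels(), collapse = ", "))
  rec
}

#' Write a recording to CSV or EDF
#'
#' @param recording a [new_recording()] object.
#' @param path destination; `.edf` selects EDF (16-bit integer coded,
#'   physical-unit scaled), anything else the headered-CSV dialect that
#'   [read_recording()] reads back.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "cog_recording"))
  if (grepl("\\.edf$", path, ignore.case = TRUE)) {
    write_edf(recording, path)
  } else {
    data.table::fwrite(data.table::as.data.table(recording$samples), path)
  }
  invisible(path)
}

#' Drop the initial, unstable portion of a recording
#'
#' The protocol excludes the first 60 s of every task recording because of
#' measurement instability right after task onset; `drop_s` is exposed rather
#' than hard-coded so the same rule can be applied (or not) to baselines.
#'
#' @param recording a [new_recording()] object.
#' @param drop_s seconds to remove from the start (default 60).
#' @return The trimmed recording, with `start_time` advanced by `drop_s`.
#' @export
trim_initial <- function(recording, drop_s = 60) {
  stopifnot(inherits(recording, "cog_recording"), drop_s >= 0)
  if (drop_s == 0) return(recording)
  n_drop <- round(drop_s * recording$fs)
  if (n_drop >= nrow(recording$samples))
    stop("recording (", duration(recording), " s) is not longer than drop_s (",
         drop_s, " s)")
  recording$samples <- recording$samples[-seq_len(n_drop), , drop = FALSE]
  recording$start_time <- recording$start_time + drop_s
  recording
}

#' Read an n-back trial log
#'
#' @param path CSV with columns `trial_index`, `digit`, `onset_s`, `response`,
#'   `rt_ms` (and optionally `correct`).
#' @param condition `"zero_back"` or `"three_back"`.
#' @param isi_s inter-stimulus interval in seconds.
#' @return A [new_task_run()] object.
#' @export
read_trials <- function(path, condition = c("zero_back", "three_back"),
                        isi_s = 3) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$response <- as.character(df$response)
  new_task_run(df, condition = match.arg(condition), isi_s = isi_s)
}

#' Write an n-back trial log
#' @param run a [new_task_run()] object.
#' @param path destination CSV.
#' @return `path`, invisibly.
#' @export
write_trials <- function(run, path) {
  stopifnot(inherits(run, "task_run"))
  write.csv(run$trials, path, row.names = FALSE)
  invisible(path)
}
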