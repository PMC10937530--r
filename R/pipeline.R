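#' Pipeline configuration
#'
#' Every tunable of the analysis pipeline in one list; the defaults are the
#' protocol values (60-s initial trim; 4-30 Hz order-424 FIR; 20-s/1-s
#' sliding Welch windows with 1-s segments; 64-128 s over 5-128 s index
#' bands; 130-s second-order windows over 40-90 s; 3-s ISI; 0.05-uS SCR
#' threshold).
#'
#' @param data_dir directory of input files (layout as [write_cohort()]).
#' @param trim_s initial seconds excluded from every signal.
#' @param filter [filter_spec()] for EEG band-limiting.
#' @param window_s,shift_s,segment_s sliding-Welch parameters (seconds).
#' @param num_band,den_band infra-slow index bands ([period_band()]).
#' @param second_window_s,second_band second-order series parameters.
#' @param scr_threshold_uS SCR detection threshold.
#' @param isi_s inter-stimulus interval.
#' @param rt_band_hz RT fluctuation summary band.
#' @param bh_q FDR level for the statistics battery.
#' @param seed seed recorded for provenance.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(data_dir = NULL, trim_s = 60,
                            filter = filter_spec(),
                            window_s = 20, shift_s = 1, segment_s = 1,
                            num_band = period_band(64, 128),
                            den_band = period_band(5, 128),
                            second_window_s = 130,
                            second_band = period_band(40, 90),
                            scr_threshold_uS = 0.05, isi_s = 3,
                            rt_band_hz = 0.05, bh_q = 0.05, seed = 1) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' EEG feature extraction for one session
#'
#' Trim, offset removal, FIR band-limiting, first-order alpha and theta
#' series, and the infra-slow index; optionally the second-order series and
#' 24-dimensional arousal features.
#'
#' @param eeg raw EEG [new_recording()].
#' @param config a [pipeline_config()].
#' @param condition task label carried into the index.
#' @param second_order also compute second-order series and arousal features?
#' @return List: `alpha_1st`, `theta_1st`, `infraslow` (and with
#'   `second_order`: `alpha_2nd`, `theta_2nd`, `features`).
#' @export
extract_eeg_features <- function(eeg, config = pipeline_config(),
                                 condition = NULL, second_order = FALSE) {
  rec <- trim_initial(eeg, config$trim_s)
  rec <- bandpass(remove_offset(rec), config$filter)
  sp <- sliding_psd(rec, config$window_s, config$shift_s, config$segment_s)
  alpha_1st <- band_fraction_series(sp, band_def("alpha"))
  theta_1st <- band_fraction_series(sp, band_def("theta"))
  out <- list(alpha_1st = alpha_1st, theta_1st = theta_1st,
              infraslow = infraslow_index(alpha_1st, config$num_band,
                                          config$den_band,
                                          condition = condition))
  if (second_order) {
    out$alpha_2nd <- second_order_series(alpha_1st, config$second_window_s,
                                         band = config$second_band)
    out$theta_2nd <- second_order_series(theta_1st, config$second_window_s,
                                         band = config$second_band)
    out$features <- build_features(alpha_1st, theta_1st,
                                   out$alpha_2nd, out$theta_2nd)
  }
  out
}

#' Summarize one participant-condition session
#'
#' Runs every applicable feature stage over in-memory session data and
#' returns one summary row. Missing modalities yield `NA` fields rather than
#' aborting (real cohorts lose modalities to sensor failures), except EEG
#' and behavior which are required.
#'
#' @param session list with elements `eeg` (recording), `ppg`
#'   (`list(recording, ...)` or recording), `eda` (likewise), `trials`
#'   (task_run); `ppg`/`eda` may be `NULL`.
#' @param config a [pipeline_config()].
#' @param participant_id identifier for the summary row.
#' @param arousal_model optional trained [train_lopo()] model; when supplied,
#'   the second-order features are built and the high-arousal portion
#'   estimated.
#' @return A one-row data.frame (a `participant_summary` row).
#' @export
run_session <- function(session, config = pipeline_config(),
                        participant_id = "P01", arousal_model = NULL) {
  stopifnot(!is.null(session$eeg), !is.null(session$trials))
  run <- session$trials
  cond <- run$condition
  feats <- extract_eeg_features(session$eeg, config, condition = cond,
                                second_order = !is.null(arousal_model))
  beh <- summarize_behavior(run)

  rmssd_ms <- NA_real_
  if (!is.null(session$ppg)) {
    ppg <- if (inherits(session$ppg, "cog_recording")) session$ppg else
      session$ppg$recording
    rmssd_ms <- rmssd(detect_pulses(trim_initial(ppg, config$trim_s)))
  }
  scr_rate <- NA_real_
  if (!is.null(session$eda)) {
    eda <- if (inherits(session$eda, "cog_recording")) session$eda else
      session$eda$recording
    scr_rate <- detect_scr(trim_initial(eda, config$trim_s),
                           config$scr_threshold_uS)$rate_per_min
  }
  high_portion <- NA_real_
  if (!is.null(arousal_model)) {
    Z <- z_normalize(feats$features)
    high_portion <- estimate_trace(arousal_model, Z)$high_portion
  }
  data.frame(participant_id = participant_id, condition = cond,
             infraslow_index = feats$infraslow$value,
             rmssd_ms = rmssd_ms, scr_rate_per_min = scr_rate,
             accuracy = beh$accuracy, mean_rt_ms = beh$mean_rt_ms,
             rt_iqr_ms = beh$rt_iqr_ms, rt_fluct_index = beh$rt_fluct_index,
             high_portion = high_portion, stringsAsFactors = FALSE)
}

#' Summarize one participant from files on disk
#'
#' Reads `<id>_<condition>_{eeg,ppg,eda,trials}` files from
#' `config$data_dir` for both conditions and summarizes each. A missing EDA
#' or PPG file leaves the corresponding fields `NA`; missing EEG or trial
#' files are errors.
#'
#' @param config a [pipeline_config()] with `data_dir` set.
#' @param participant_id file-name stem of the participant.
#' @param arousal_model optional, see [run_session()].
#' @return Two-row data.frame (one row per condition).
#' @export
run_participant <- function(config, participant_id, arousal_model = NULL) {
  stopifnot(!is.null(config$data_dir))
  rows <- lapply(c("zero_back", "three_back"), function(cond) {
    stem <- file.path(config$data_dir, paste(participant_id, cond, sep = "_"))
    first_existing <- function(suffixes) {
      for (s in suffixes) if (file.exists(paste0(stem, s)))
        return(paste0(stem, s))
      NULL
    }
    eeg_path <- first_existing(c("_eeg.csv", "_eeg.edf"))
    trials_path <- first_existing("_trials.csv")
    if (is.null(eeg_path) || is.null(trials_path))
      stop("missing EEG or trial log for ", participant_id, " / ", cond)
    session <- list(
      eeg = read_recording(eeg_path, "EEG"),
      trials = read_trials(trials_path, condition = cond,
                           isi_s = config$isi_s))
    ppg_path <- first_existing("_ppg.csv")
    if (!is.null(ppg_path)) session$ppg <- read_recording(ppg_path, "PPG")
    eda_path <- first_existing("_eda.csv")
    if (!is.null(eda_path)) session$eda <- read_recording(eda_path, "EDA")
    run_session(session, config, participant_id, arousal_model)
  })
  do.call(rbind, rows)
}

#' Difference-score statistics battery over a summary table
#'
#' The protocol's correlation analyses: three-back accuracy against the
#' condition differences (three-back minus zero-back) of the infra-slow
#' index, RT interquartile range, RT fluctuation index and SCR rate, and
#' against three-back RMSSD; Benjamini-Hochberg correction across the
#' family. Tests whose preconditions fail (missing modality, degenerate
#' variance) are reported as failed rows, not raised.
#'
#' @param summary_table rows from [run_session()]/[run_participant()].
#' @param q FDR level.
#' @return data.frame with `var_a`, `var_b`, `r`, `p`, `adj_p`, `n`, `note`.
#' @export
cohort_statistics <- function(summary_table, q = 0.05) {
  battery <- list(
    list("accuracy", "infraslow_index", c(FALSE, TRUE)),
    list("accuracy", "rmssd_ms", c(FALSE, FALSE)),
    list("accuracy", "rt_iqr_ms", c(FALSE, TRUE)),
    list("accuracy", "scr_rate_per_min", c(FALSE, TRUE)),
    list("infraslow_index", "rt_iqr_ms", c(TRUE, TRUE)),
    list("infraslow_index", "rt_fluct_index", c(TRUE, TRUE)))
  rows <- lapply(battery, function(b) {
    res <- tryCatch(diff_correlation(summary_table, b[[1]], b[[2]], b[[3]]),
                    error = function(e) e)
    if (inherits(res, "error"))
      data.frame(var_a = b[[1]], var_b = b[[2]], r = NA_real_, p = NA_real_,
                 n = NA_integer_, note = conditionMessage(res),
                 stringsAsFactors = FALSE)
    else
      data.frame(var_a = b[[1]], var_b = b[[2]], r = res$statistic,
                 p = res$p_value, n = res$n, note = "",
                 stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adj_p <- NA_real_
  ok <- !is.na(out$p)
  if (any(ok)) out$adj_p[ok] <- bh_adjust(out$p[ok], q)$adj_p
  out[, c("var_a", "var_b", "r", "p", "adj_p", "n", "note")]
}

#' Run the full pipeline over a cohort
#'
#' Summarizes every participant (from `config$data_dir` files, or an
#' in-memory [synth_cohort()] via `cohort`), then runs the paired-comparison
#' and difference-score correlation battery.
#'
#' @param config a [pipeline_config()].
#' @param cohort optional in-memory cohort (bypasses `data_dir`).
#' @param arousal_model optional, see [run_session()].
#' @return List: `summary` (participant x condition table), `statistics`
#'   (correlation battery), `paired` (three-back vs zero-back paired tests
#'   per index), `config`.
#' @export
run_cohort <- function(config = pipeline_config(), cohort = NULL,
                       arousal_model = NULL) {
  if (is.null(cohort)) {
    stopifnot(!is.null(config$data_dir))
    files <- list.files(config$data_dir, pattern = "_trials\\.csv$")
    ids <- sort(unique(sub("_(zero|three)_back_trials\\.csv$", "", files)))
    if (length(ids) < 4) stop("need >= 4 participants, found ", length(ids))
    summary <- do.call(rbind, lapply(ids, function(id)
      run_participant(config, id, arousal_model)))
  } else {
    summary <- do.call(rbind, lapply(names(cohort$sessions), function(id) {
      do.call(rbind, lapply(cohort$sessions[[id]], run_session,
                            config = config, participant_id = id,
                            arousal_model = arousal_model))
    }))
  }
  rownames(summary) <- NULL
  paired_vars <- c("infraslow_index", "accuracy", "mean_rt_ms", "rt_iqr_ms",
                   "rt_fluct_index", "rmssd_ms")
  paired <- lapply(stats::setNames(paired_vars, paired_vars), function(v) {
    tryCatch({
      x <- condition_scores(summary, v, diff = FALSE)
      zb <- summary[summary$condition == "zero_back", ]
      y <- stats::setNames(zb[[v]], zb$participant_id)[names(x)]
      paired_test(x, y)
    }, error = function(e) conditionMessage(e))
  })
  list(summary = summary, statistics = cohort_statistics(summary, config$bh_q),
       paired = paired, config = config)
}
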