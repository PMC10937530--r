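# Seeded generators emulating the target protocol's recordings: 6-min, 6-channel
# frontal EEG with infra-slow amplitude modulation of the alpha rhythm,
# pulse waveforms with controllable beat-to-beat variability, SCR-like
# electrodermal transients, and 200-trial n-back behavior at a 3-s ISI.
# Every generator is deterministic given its seed and returns its ground
# truth, so each pipeline stage can be validated against known structure.

# 1/f^exponent Gaussian noise via spectral shaping, unit RMS
noise_1f <- function(n, exponent = 1) {
  spec <- fft(rnorm(n))
  f <- c(1, seq_len(n - 1))                      # guard DC
  f <- pmin(f, n - f + 1)                        # two-sided frequency index
  spec <- spec * f^(-exponent / 2)
  spec[1] <- 0
  x <- Re(fft(spec, inverse = TRUE)) / n
  x / sd(x)
}

# narrowband Gaussian process: white noise spectrally confined to
# [low, high] Hz with raised-cosine edges (taper_hz wide), unit RMS
narrowband <- function(n, fs, low, high, taper_hz = 0.5) {
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)                           # two-sided
  gain <- numeric(n)
  core <- f >= low & f <= high
  gain[core] <- 1
  lo_edge <- f >= low - taper_hz & f < low
  gain[lo_edge] <- 0.5 + 0.5 * cos(pi * (low - f[lo_edge]) / taper_hz)
  hi_edge <- f > high & f <= high + taper_hz
  gain[hi_edge] <- 0.5 + 0.5 * cos(pi * (f[hi_edge] - high) / taper_hz)
  x <- Re(fft(fft(rnorm(n)) * gain, inverse = TRUE)) / n
  x / sd(x)
}

#' Synthetic frontal EEG with infra-slow alpha modulation
#'
#' Six channels, each the sum of 1/f background noise, a narrowband theta
#' process, and a narrowband alpha process whose amplitude envelope is
#' `1 + depth * sin(2*pi*t/period + phase)` — the multiplicative modulation
#' acts on the alpha component only, matching the construct of infra-slow
#' fluctuations of alpha power. The envelope (random phase) is shared across
#' channels, as a brain-wide slow modulation would be.
#'
#' @param duration_s recording length in seconds (protocol task length: 360).
#' @param fs sampling rate (protocol: 256 Hz).
#' @param alpha_amp,theta_amp RMS amplitude of the alpha/theta components
#'   (arbitrary microvolt units).
#' @param noise_amp RMS amplitude of the 1/f background.
#' @param noise_1f_exponent spectral exponent of the background.
#' @param modulation_depth alpha envelope modulation depth in `[0, 1]`.
#' @param modulation_period_s envelope period in seconds (default 100, inside
#'   the 64-128 s analysis band).
#' @param offset_uV constant DC offset added to every channel (removed by
#'   [remove_offset()]).
#' @param seed RNG seed.
#' @return A 6-channel EEG [new_recording()]; the generation parameters and
#'   envelope phase are attached as attribute `ground_truth`.
#' @export
synth_eeg <- function(duration_s = 360, fs = 256, alpha_amp = 5,
                      theta_amp = 5, noise_amp = 14, noise_1f_exponent = 1,
                      modulation_depth = 0.5, modulation_period_s = 100,
                      offset_uV = 50, seed = NULL) {
  if (modulation_depth < 0 || modulation_depth > 1)
    stop("modulation_depth must lie in [0, 1] (the envelope must stay positive)")
  with_seed(seed, {
    n <- round(duration_s * fs)
    t <- (seq_len(n) - 1) / fs
    phase <- runif(1, 0, 2 * pi)
    env <- 1 + modulation_depth * sin(2 * pi * t / modulation_period_s + phase)
    samples <- vapply(seq_len(6), function(ch) {
      noise_amp * noise_1f(n, noise_1f_exponent) +
        theta_amp * narrowband(n, fs, 4, 7) +
        alpha_amp * env * narrowband(n, fs, 8, 13) +
        offset_uV
    }, numeric(n))
    rec <- new_recording(samples, fs = fs, channel_labels = eeg_channels(),
                         modality = "EEG")
    attr(rec, "ground_truth") <- list(modulation_depth = modulation_depth,
                                      modulation_period_s = modulation_period_s,
                                      envelope_phase = phase,
                                      alpha_amp = alpha_amp,
                                      theta_amp = theta_amp,
                                      noise_amp = noise_amp)
    rec
  })
}

# smooth pulse template: systolic peak + dicrotic bump, peak at t = 0
ppg_template <- function(fs) {
  t <- seq(-0.4, 0.6, by = 1 / fs)
  w <- exp(-0.5 * (t / 0.045)^2) + 0.35 * exp(-0.5 * ((t - 0.25) / 0.07)^2)
  list(t = t, w = w, peak_idx = which.max(w))
}

#' Synthetic photoplethysmogram with known beat times
#'
#' A train of smooth pulse templates at sinusoidally modulated inter-beat
#' intervals plus optional white interval jitter and additive measurement
#' noise. The interval before the beat at time t is
#' `mean_ibi_ms + rsa_amp_ms * sin(2*pi*rsa_freq_hz*t) + jitter`.
#'
#' @param duration_s recording length (seconds).
#' @param fs sampling rate (protocol: 512 Hz).
#' @param mean_ibi_ms mean inter-beat interval (500-1500 ms).
#' @param rsa_amp_ms amplitude of the sinusoidal interval modulation
#'   (respiratory sinus arrhythmia surrogate); must be < `mean_ibi_ms`/2.
#' @param rsa_freq_hz modulation frequency (default 0.25 Hz).
#' @param jitter_ms SD of white interval jitter.
#' @param noise_sd SD of additive Gaussian measurement noise (template peak
#'   height is 1).
#' @param seed RNG seed.
#' @return List: `recording` (single-channel PPG) and `beat_times_s` (ground
#'   truth, template-peak times).
#' @export
synth_ppg <- function(duration_s = 360, fs = 512, mean_ibi_ms = 800,
                      rsa_amp_ms = 40, rsa_freq_hz = 0.25, jitter_ms = 0,
                      noise_sd = 0, seed = NULL) {
  if (mean_ibi_ms < 500 || mean_ibi_ms > 1500)
    stop("mean_ibi_ms must lie in [500, 1500]")
  if (rsa_amp_ms >= mean_ibi_ms / 2)
    stop("rsa_amp_ms must be < mean_ibi_ms / 2")
  with_seed(seed, {
    beats <- numeric(0)
    t <- 0.5
    while (t < duration_s - 0.7) {
      beats <- c(beats, t)
      ibi <- mean_ibi_ms + rsa_amp_ms * sin(2 * pi * rsa_freq_hz * t) +
        if (jitter_ms > 0) rnorm(1, 0, jitter_ms) else 0
      t <- t + ibi / 1000
    }
    n <- round(duration_s * fs)
    x <- numeric(n)
    tpl <- ppg_template(fs)
    for (b in beats) {
      i0 <- round(b * fs) + 1L - (tpl$peak_idx - 1L)
      idx <- i0:(i0 + length(tpl$w) - 1L)
      ok <- idx >= 1L & idx <= n
      x[idx[ok]] <- x[idx[ok]] + tpl$w[ok]
    }
    if (noise_sd > 0) x <- x + rnorm(n, 0, noise_sd)
    rec <- new_recording(x, fs = fs, channel_labels = "PPG",
                         modality = "PPG")
    list(recording = rec, beat_times_s = beats)
  })
}

# SCR shape: difference of exponentials, unit peak, onset at t = 0
scr_template <- function(fs, tau_rise = 0.75, tau_decay = 3, len_s = 15) {
  t <- seq(0, len_s, by = 1 / fs)
  w <- exp(-t / tau_decay) - exp(-t / tau_rise)
  w / max(w)
}

#' Synthetic electrodermal activity with known SCR events
#'
#' Tonic level plus slow drift plus SCR-shaped transients (difference of
#' exponentials, ~2-s rise) at the given onset times, with additive
#' measurement noise.
#'
#' @param duration_s recording length (seconds).
#' @param fs sampling rate (protocol: 512 Hz).
#' @param scr_onsets_s SCR onset times; `NULL` draws `n_scr` onsets uniformly
#'   with >= 12 s separation.
#' @param n_scr number of events when `scr_onsets_s` is `NULL`.
#' @param amplitude_uS SCR amplitude(s), recycled over events.
#' @param tonic_uS tonic conductance level.
#' @param drift_uS amplitude of a very slow (240-s period) tonic drift.
#' @param noise_sd additive noise SD.
#' @param seed RNG seed.
#' @return List: `recording` (single-channel EDA) and `scr_onsets_s` (ground
#'   truth).
#' @export
synth_eda <- function(duration_s = 360, fs = 512, scr_onsets_s = NULL,
                      n_scr = 8, amplitude_uS = 0.2, tonic_uS = 2,
                      drift_uS = 0.1, noise_sd = 0.003, seed = NULL) {
  with_seed(seed, {
    if (is.null(scr_onsets_s)) {
      grid <- seq(10, duration_s - 20, by = 12)
      if (n_scr > length(grid))
        stop("cannot place ", n_scr, " SCRs >= 12 s apart in ", duration_s, " s")
      scr_onsets_s <- sort(sample(grid, n_scr)) + runif(n_scr, 0, 4)
    }
    n <- round(duration_s * fs)
    t <- (seq_len(n) - 1) / fs
    x <- tonic_uS + drift_uS * sin(2 * pi * t / 240 + runif(1, 0, 2 * pi))
    tpl <- scr_template(fs)
    amps <- rep_len(amplitude_uS, length(scr_onsets_s))
    for (k in seq_along(scr_onsets_s)) {
      i0 <- round(scr_onsets_s[k] * fs) + 1L
      idx <- i0:min(i0 + length(tpl) - 1L, n)
      x[idx] <- x[idx] + amps[k] * tpl[seq_along(idx)]
    }
    if (noise_sd > 0) x <- x + rnorm(n, 0, noise_sd)
    rec <- new_recording(x, fs = fs, channel_labels = "EDA",
                         modality = "EDA")
    list(recording = rec, scr_onsets_s = scr_onsets_s)
  })
}

#' Synthetic n-back behavioral run
#'
#' Uniform random digits presented at the inter-stimulus interval; responses
#' are correct with probability `accuracy_true` (independently per trial) and
#' otherwise inverted; reaction times are base + slow sinusoidal drift +
#' white noise, floored at 150 ms.
#'
#' @param n_trials number of trials (protocol: 200).
#' @param isi_s inter-stimulus interval (protocol: 3 s).
#' @param condition `"zero_back"` or `"three_back"`.
#' @param accuracy_true per-trial probability of a correct response.
#' @param rt_base_ms mean reaction time.
#' @param rt_noise_ms SD of white RT noise.
#' @param rt_drift_amp_ms amplitude of a sinusoidal RT drift.
#' @param rt_drift_period_s period of the drift (default 50 s, inside the
#'   < 0.05 Hz band summarized by [rt_fluctuation_spectrum()]).
#' @param omission_rate probability a trial has no response.
#' @param seed RNG seed.
#' @return A [new_task_run()]; `accuracy_true` attached as attribute
#'   `ground_truth`.
#' @export
synth_behavior <- function(n_trials = 200, isi_s = 3,
                           condition = c("three_back", "zero_back"),
                           accuracy_true = 0.9, rt_base_ms = 600,
                           rt_noise_ms = 80, rt_drift_amp_ms = 0,
                           rt_drift_period_s = 50, omission_rate = 0,
                           seed = NULL) {
  condition <- match.arg(condition)
  stopifnot(accuracy_true >= 0, accuracy_true <= 1)
  with_seed(seed, {
    digit <- sample(0:9, n_trials, replace = TRUE)
    onset <- (seq_len(n_trials) - 1) * isi_s
    if (condition == "three_back") {
      truth <- rep(NA_character_, n_trials)
      idx <- seq_len(n_trials)[-(1:3)]
      truth[idx] <- ifelse(digit[idx] == digit[idx - 3L], "match", "nonmatch")
      flip <- c(match = "nonmatch", nonmatch = "match")
    } else {
      truth <- ifelse(digit %% 2 == 0, "even", "odd")
      flip <- c(even = "odd", odd = "even")
    }
    correct_draw <- runif(n_trials) < accuracy_true
    response <- ifelse(is.na(truth), unname(flip[1]),
                       ifelse(correct_draw, truth, unname(flip[truth])))
    t_mid <- onset
    rt <- rt_base_ms +
      rt_drift_amp_ms * sin(2 * pi * t_mid / rt_drift_period_s +
                              runif(1, 0, 2 * pi)) +
      rnorm(n_trials, 0, rt_noise_ms)
    rt <- pmax(rt, 150)
    if (omission_rate > 0) {
      om <- runif(n_trials) < omission_rate
      response[om] <- "none"
      rt[om] <- NA
    }
    run <- new_task_run(
      data.frame(trial_index = seq_len(n_trials), digit = digit,
                 onset_s = onset, response = response, rt_ms = rt,
                 stringsAsFactors = FALSE),
      condition = condition, isi_s = isi_s)
    attr(run, "ground_truth") <- list(accuracy_true = accuracy_true,
                                      rt_drift_amp_ms = rt_drift_amp_ms,
                                      rt_drift_period_s = rt_drift_period_s)
    run
  })
}

#' Synthetic labeled arousal feature sessions
#'
#' Feature vectors for exercising the SVM harness: per participant, a random
#' participant-level offset plus Gaussian clusters for the low and high
#' arousal states whose means are `separation_sd` apart (in within-cluster SD
#' units, spread evenly over dimensions).
#'
#' @param n_participants number of participants (>= 3 for LOPO).
#' @param n_per_state vectors per state per participant.
#' @param separation_sd distance between state means in SD units.
#' @param n_dims feature dimensionality (default 24).
#' @param participant_sd SD of the participant-level offset.
#' @param seed RNG seed.
#' @return List: `X` (matrix), `labels` (`"low"`/`"high"`), `participants`.
#' @export
synth_arousal_features <- function(n_participants = 8, n_per_state = 60,
                                   separation_sd = 4, n_dims = 24,
                                   participant_sd = 0.5, seed = NULL) {
  with_seed(seed, {
    shift <- rep(separation_sd / sqrt(n_dims), n_dims)
    rows <- n_participants * 2 * n_per_state
    X <- matrix(0, rows, n_dims)
    labels <- character(rows)
    participants <- character(rows)
    r <- 0L
    for (p in seq_len(n_participants)) {
      off <- rnorm(n_dims, 0, participant_sd)
      for (state in c("low", "high")) {
        mu <- off + if (state == "high") shift else 0
        idx <- r + seq_len(n_per_state)
        X[idx, ] <- matrix(rnorm(n_per_state * n_dims), n_per_state) +
          matrix(mu, n_per_state, n_dims, byrow = TRUE)
        labels[idx] <- state
        participants[idx] <- paste0("P", p)
        r <- r + n_per_state
      }
    }
    colnames(X) <- paste0("f", seq_len(n_dims))
    list(X = X, labels = labels, participants = participants)
  })
}

#' Cohort specification for end-to-end synthesis
#'
#' Defaults mirror the protocol conditions: 12 participants, 6-min tasks, a
#' 100-s alpha modulation period, and a latent trait that jointly drives the
#' condition difference in modulation depth and three-back accuracy with
#' target correlation `trait_rho` (Gaussian copula). The three-back/zero-back
#' contrasts (deeper modulation, lower accuracy, slower and more variable
#' RTs, more SCRs under load) follow the expected direction of load effects.
#'
#' @param n_participants cohort size (>= 4).
#' @param trait_rho target correlation between the latent infra-slow
#'   enhancement and three-back accuracy, in `[-1, 1]`.
#' @param duration_s task length in seconds.
#' @param modulation_period_s alpha envelope period (inside 64-128 s).
#' @param depth_zero zero-back modulation depth (common to everyone).
#' @param depth_three_range three-back depth spans this range as the latent
#'   trait runs over its distribution.
#' @param accuracy_range three-back true accuracy range, likewise.
#' @param noise_1f_exponent EEG background exponent.
#' @param mean_ibi_ms,rsa_amp_range_ms pulse generator settings.
#' @param scr_rate_per_min named per-condition SCR rates.
#' @param seed RNG seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_participants = 12, trait_rho = 0.7,
                        duration_s = 360, modulation_period_s = 100,
                        depth_zero = 0.1, depth_three_range = c(0.1, 0.45),
                        accuracy_range = c(0.6, 0.95),
                        noise_1f_exponent = 1, mean_ibi_ms = 800,
                        rsa_amp_range_ms = c(20, 60),
                        scr_rate_per_min = c(zero_back = 1.5, three_back = 3),
                        seed = 1) {
  if (n_participants < 4) stop("need >= 4 participants")
  if (abs(trait_rho) > 1) stop("|trait_rho| must be <= 1")
  structure(as.list(environment()), class = "cohort_spec")
}

#' Generate a full synthetic cohort
#'
#' For each participant a latent bivariate-normal pair `(u, v)` with
#' correlation `trait_rho` sets the three-back modulation depth (from `u`)
#' and the three-back true accuracy (from `v`); EEG, PPG, EDA and behavior
#' are then generated per condition. All ground truths are returned so
#' recovery of the induced depth-accuracy association through the full
#' pipeline can be checked.
#'
#' @param spec a [cohort_spec()].
#' @param modalities which modalities to generate (subset of
#'   `c("eeg", "ppg", "eda", "behavior")`); restricting modalities speeds up
#'   large simulation studies that only consume part of the pipeline.
#' @return A `cohort` list: `sessions` (nested by participant, then
#'   condition: `eeg`, `ppg`, `eda`, `trials` as generated), `ground_truth`
#'   data.frame, `spec`.
#' @export
synth_cohort <- function(spec = cohort_spec(),
                         modalities = c("eeg", "ppg", "eda", "behavior")) {
  stopifnot(inherits(spec, "cohort_spec"))
  modalities <- match.arg(modalities, several.ok = TRUE)
  with_seed(spec$seed, {
    n <- spec$n_participants
    z <- matrix(rnorm(2 * n), n)
    u <- z[, 1]
    v <- spec$trait_rho * z[, 1] + sqrt(1 - spec$trait_rho^2) * z[, 2]
    depth3 <- spec$depth_three_range[1] +
      diff(spec$depth_three_range) * pnorm(u)
    acc3 <- spec$accuracy_range[1] + diff(spec$accuracy_range) * pnorm(v)
    ids <- sprintf("P%02d", seq_len(n))
    session_seeds <- matrix(sample.int(.Machine$integer.max %/% 2, 2 * n),
                            n, 2)
    sessions <- list()
    gt <- list()
    for (i in seq_len(n)) {
      per_cond <- list()
      for (ci in 1:2) {
        cond <- c("zero_back", "three_back")[ci]
        cseed <- session_seeds[i, ci]
        depth <- if (cond == "three_back") depth3[i] else spec$depth_zero
        acc <- if (cond == "three_back") acc3[i] else
          runif(1, 0.92, 0.99)
        rsa <- runif(1, spec$rsa_amp_range_ms[1], spec$rsa_amp_range_ms[2])
        ses <- list()
        if ("eeg" %in% modalities)
          ses$eeg <- synth_eeg(duration_s = spec$duration_s,
                               modulation_depth = depth,
                               modulation_period_s = spec$modulation_period_s,
                               noise_1f_exponent = spec$noise_1f_exponent,
                               seed = cseed)
        if ("ppg" %in% modalities)
          ses$ppg <- synth_ppg(duration_s = spec$duration_s,
                               mean_ibi_ms = spec$mean_ibi_ms,
                               rsa_amp_ms = rsa, jitter_ms = 5,
                               noise_sd = 0.05, seed = cseed + 1L)
        if ("eda" %in% modalities)
          ses$eda <- synth_eda(duration_s = spec$duration_s,
                               n_scr = rpois(1, spec$scr_rate_per_min[[cond]] *
                                               spec$duration_s / 60),
                               seed = cseed + 2L)
        if ("behavior" %in% modalities)
          ses$trials <- synth_behavior(
            condition = cond, accuracy_true = acc,
            rt_base_ms = if (cond == "three_back") 620 else 450,
            rt_noise_ms = if (cond == "three_back") 90 else 50,
            rt_drift_amp_ms = if (cond == "three_back") 100 else 30,
            seed = cseed + 3L)
        per_cond[[cond]] <- ses
        gt[[length(gt) + 1L]] <- data.frame(
          participant_id = ids[i], condition = cond,
          modulation_depth = depth, accuracy_true = acc,
          rsa_amp_ms = rsa, stringsAsFactors = FALSE)
      }
      sessions[[ids[i]]] <- per_cond
    }
    structure(list(sessions = sessions,
                   ground_truth = do.call(rbind, gt), spec = spec),
              class = "cohort")
  })
}

#' Write a synthetic cohort to disk in the layouts the io module reads
#'
#' One file per participant x condition x modality:
#' `<id>_<condition>_eeg.csv` (or `.edf`), `_ppg.csv`, `_eda.csv`,
#' `_trials.csv`, plus `ground_truth.csv`.
#'
#' @param cohort a [synth_cohort()] result.
#' @param dir output directory (created if missing).
#' @param eeg_format `"csv"` or `"edf"`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, eeg_format = c("csv", "edf")) {
  eeg_format <- match.arg(eeg_format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(cohort$sessions)) {
    for (cond in names(cohort$sessions[[id]])) {
      ses <- cohort$sessions[[id]][[cond]]
      stem <- file.path(dir, paste(id, cond, sep = "_"))
      if (!is.null(ses$eeg))
        write_recording(ses$eeg, paste0(stem, "_eeg.", eeg_format))
      if (!is.null(ses$ppg))
        write_recording(ses$ppg$recording, paste0(stem, "_ppg.csv"))
      if (!is.null(ses$eda))
        write_recording(ses$eda$recording, paste0(stem, "_eda.csv"))
      if (!is.null(ses$trials))
        write_trials(ses$trials, paste0(stem, "_trials.csv"))
    }
  }
  write.csv(cohort$ground_truth, file.path(dir, "ground_truth.csv"),
            row.names = FALSE)
  invisible(dir)
}
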