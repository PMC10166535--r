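#' Extract the seven drowsiness measures from one session recording
#'
#' Runs the full per-trial extraction chain on a [recording()]: trial slicing
#' anchored on the KSS prompts, EOG-to-angle conversion and slow-eye-movement
#' detection (%SEM), EEG preprocessing / artifact-screened segmentation /
#' Welch band power (alpha, theta), PERCLOS against the participant's
#' baseline pupil diameter, and SDLP.  A missing channel leaves the
#' corresponding measure `NA` and the run continues.
#'
#' @param rec A [recording()].
#' @param calibration An [calibrate_eog()] result for this session's block
#'   (pre-session-1 calibration for sessions 1-3, pre-session-4 for 4-8), or
#'   `NULL` to skip the EOG-derived measure.
#' @param baseline A [baseline_pupil_max()] result, or `NULL` to skip
#'   PERCLOS.
#' @param ratings Optional list with one `segments x raters` point matrix per
#'   trial (see [simulate_raters()] or [read_rater_files()]); `NULL` leaves
#'   `ord_mean` missing.
#' @param config An [analysis_config()].
#' @return A `data.frame` with one row per trial and the measure-table
#'   columns.
#' @export
extract_measures <- function(rec, calibration = NULL, baseline = NULL,
                             ratings = NULL, config = analysis_config()) {
  stopifnot(inherits(rec, "recording"))
  trials <- slice_trials(rec)
  n <- nrow(trials)
  out <- trials[c("participant_id", "session", "trial", "kss")]

  out$sem_pct <- NA_real_
  if (!is.null(calibration) && "eog_h" %in% names(rec$channels)) {
    angle <- eog_to_angle(rec$channels$eog_h, calibration, config)
    episodes <- detect_sem(angle, config)
    out$sem_pct <- vapply(seq_len(n), function(i) {
      percent_sem(episodes, trials$start_time[i], trials$end_time[i])
    }, numeric(1))
  }

  out$eeg_alpha_power <- out$eeg_theta_power <- NA_real_
  if ("eeg_c3" %in% names(rec$channels)) {
    filt <- preprocess_eeg(rec$channels$eeg_c3, config)
    for (i in seq_len(n)) {
      segs <- withCallingHandlers(
        segment_trial_eeg(filt, trials$start_time[i], trials$end_time[i],
                          config),
        warning = function(w) invokeRestart("muffleWarning"))
      fs <- filt$sampling_rate
      out$eeg_alpha_power[i] <- trial_bandpower(segs, config$alpha_band, fs,
                                                config)
      out$eeg_theta_power[i] <- trial_bandpower(segs, config$theta_band, fs,
                                                config)
    }
  }

  out$perclos_pct <- NA_real_
  if (!is.null(baseline) && "pupil_diameter" %in% names(rec$channels)) {
    out$perclos_pct <- vapply(seq_len(n), function(i) {
      suppressWarnings(
        perclos(rec$channels$pupil_diameter, baseline,
                trials$start_time[i], trials$end_time[i],
                config)$perclos_pct)
    }, numeric(1))
  }

  out$sdlp_cm <- NA_real_
  if ("lane_position" %in% names(rec$channels)) {
    out$sdlp_cm <- vapply(seq_len(n), function(i) {
      suppressWarnings(sdlp(rec$channels$lane_position,
                            trials$start_time[i], trials$end_time[i]))
    }, numeric(1))
  }

  out$ord_mean <- NA_real_
  if (!is.null(ratings)) {
    stopifnot(length(ratings) == n)
    out$ord_mean <- vapply(ratings, trial_ord_score, numeric(1))
  }
  out[c("participant_id", "session", "trial", "ord_mean", "kss", "sdlp_cm",
        "perclos_pct", "sem_pct", "eeg_alpha_power", "eeg_theta_power")]
}

#' Simulate and extract a full cohort, one session at a time
#'
#' The end-to-end pipeline on synthetic data: generates each
#' participant-session [recording()] with [simulate_recording()], extracts
#' the seven measures with [extract_measures()], and discards the waveforms
#' before moving on, so memory stays bounded regardless of cohort size.
#' Calibration blocks follow the study protocol: the pre-session-1 block is
#' applied to sessions 1-3 and the pre-session-4 block to sessions 4-8.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param progress Print one line per participant?
#' @return A measure table with
#'   `n_participants * n_sessions * trials_per_session` rows.
#' @export
#' @examples
#' \donttest{
#' tab <- extract_cohort(sim_config(n_participants = 2, n_sessions = 2),
#'                       seed = 1)
#' nrow(tab)  # 2 * 2 * 3
#' }
extract_cohort <- function(config = sim_config(), seed = 1,
                           progress = FALSE) {
  acfg <- analysis_config()
  lat <- simulate_latent(config, seed)
  set.seed(.sub_seed(seed, 6))
  biases <- stats::rnorm(config$n_raters, 0, config$rater_bias_sd)
  rows <- vector("list", length(lat) * config$n_sessions)
  k <- 0L
  for (lp in lat) {
    if (progress) message("participant ", lp$participant_id)
    cals <- lapply(1:2, function(b) {
      cb <- simulate_calibration(lp, b, config, seed)
      calibrate_eog(cb$eog, cb$schedule, cb$viewing_distance_cm)
    })
    base <- baseline_pupil_max(simulate_pupil_reference(lp, config, seed),
                               acfg)
    for (s in seq_len(config$n_sessions)) {
      rec <- simulate_recording(lp, s, config, seed)
      ratings <- simulate_raters(lp, s, config, seed, biases)
      k <- k + 1L
      rows[[k]] <- suppressWarnings(
        extract_measures(rec, cals[[if (s <= 3) 1 else 2]], base, ratings,
                         acfg))
      rm(rec)
    }
  }
  assemble_measure_table(do.call(rbind, rows))
}

#' Read / write a signal channel as columnar text
#'
#' Plain-text interchange for single channels: a header line
#' `time_s,value[,valid]` followed by one row per sample.  Sampling rate is
#' recovered from the median time step.
#'
#' @param path File path.
#' @param name Channel name to assign on read.
#' @return [read_channel_file()] returns a [channel()];
#'   [write_channel_file()] returns `path` invisibly.
#' @export
read_channel_file <- function(path, name) {
  d <- utils::read.csv(path)
  stopifnot(all(c("time_s", "value") %in% names(d)), nrow(d) >= 2)
  fs <- 1 / stats::median(diff(d$time_s))
  channel(name, fs, d$value, start_time = d$time_s[1],
          validity = if ("valid" %in% names(d)) as.logical(d$valid) else NULL)
}

#' @rdname read_channel_file
#' @param x A [channel()] to write.
#' @export
write_channel_file <- function(x, path) {
  d <- data.frame(time_s = channel_times(x), value = x$values)
  if (!is.null(x$validity)) d$valid <- as.integer(x$validity)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read per-rater ORD label files
#'
#' Each rater file is columnar text `segment_start_s,label` with labels
#' `D1`-`D5` or `S` for consecutive 5-s segments of one trial.
#'
#' @param paths Character vector of per-rater file paths.
#' @return A `segments x raters` integer point matrix.
#' @export
read_rater_files <- function(paths) {
  cols <- lapply(paths, function(p) {
    d <- utils::read.csv(p, stringsAsFactors = FALSE)
    stopifnot(all(c("segment_start_s", "label") %in% names(d)))
    labels_to_points(d$label[order(d$segment_start_s)])
  })
  len <- vapply(cols, length, integer(1))
  if (length(unique(len)) != 1L) stop("rater files cover unequal segment counts")
  m <- do.call(cbind, cols)
  colnames(m) <- basename(paths)
  m
}
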