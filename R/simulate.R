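#' Simulation configuration for the synthetic driving cohort
#'
#' Parameters of the synthetic cohort generator.  The generator emulates the
#' study design — `n_participants` participants each performing
#' `n_sessions` sessions of `trials_per_session` five-minute driving trials
#' (three sessions before and five after a lunch break) — driven by a latent
#' drowsiness process that jointly couples all seven measures.  Defaults
#' reproduce the study's structural constants (17 x 8 x 3 design, 1-kHz
#' EOG/EEG, 60-Hz pupil tracking, 10-Hz lane position, three raters, 5-s
#' rating segments).
#'
#' @param n_participants Number of participants (>= 2).
#' @param n_sessions Sessions per participant.
#' @param trials_per_session Five-minute trials per session.
#' @param trial_s Trial duration, seconds.
#' @param gap_s Straight-road gap after each trial (KSS response segment),
#'   seconds.
#' @param fs_eog,fs_eeg,fs_pupil,fs_lane Channel sampling rates, Hz.
#' @param intercept_mean,intercept_sd Participant latent intercept
#'   distribution (latent units; 0 maps to the logistic midpoint).
#' @param session_step Latent increase per session within a block.
#' @param post_lunch_reset Latent offset at the first post-lunch session
#'   (the lunch break resets the between-session build-up to this value).
#' @param trial_drift Within-session latent drift per trial.
#' @param ar_phi,ar_sd First-order autoregressive latent noise at 1 Hz:
#'   lag-one coefficient and stationary standard deviation.
#' @param n_raters Number of ORD raters.
#' @param rater_bias_sd,rater_noise_sd Rater bias (drawn once per rater) and
#'   per-segment rating noise, latent units.
#' @param ord_coupling,kss_coupling Multiplier on the latent term entering
#'   the ORD and KSS response models (0 decouples them).
#' @param kss_noise_sd Latent noise added at each KSS prompt.
#' @param sem_base_rate,sem_gain Slow-eye-movement episode rate:
#'   `base + gain * sigma(d)` episodes per minute.
#' @param sem_speed_range,sem_excursion_range SEM drift speed (deg/s) and net
#'   excursion (deg) ranges, sampled uniformly.
#' @param saccade_rate Fast-saccade rate, per minute.
#' @param saccade_speed Saccade speed, deg/s.
#' @param saccade_amp_range Saccade amplitude range, deg.
#' @param volts_per_degree_range Per-participant EOG proportionality constant
#'   range, microvolts per degree.
#' @param eog_noise_uv EOG measurement noise, microvolts (sd).
#' @param pupil_base_mean,pupil_base_sd Per-participant baseline pupil
#'   diameter distribution, mm.
#' @param closure_base_rate,closure_gain Eye-closure episode rate:
#'   `base + gain * sigma(d)` per minute.
#' @param closure_meanlog,closure_sdlog Log-normal closure duration
#'   parameters (seconds).
#' @param closure_frac Pupil diameter during closure as a fraction of
#'   baseline.
#' @param closure_invalid_prob Probability a sample during closure is flagged
#'   invalid (tracking loss).
#' @param dropout_rate,dropout_dur_range Isolated tracking-loss runs
#'   unrelated to closures: rate per minute and duration range (s).
#' @param pupil_noise_sd Pupil measurement noise, mm.
#' @param eeg_bg_sd EEG background (1/f-like) amplitude, microvolts (sd).
#' @param alpha_gain,theta_gain Burst amplitude per unit `sigma(d)`,
#'   microvolts, for the 10-Hz alpha and 6-Hz theta bursts.
#' @param burst_duty Probability a 2-s block contains a burst.
#' @param eeg_noise_uv Broadband EEG sensor noise, microvolts (sd).
#' @param artifact_rate,artifact_amp_uv,artifact_dur_s Movement-artifact
#'   pulses: rate per minute, amplitude (uV), duration (s).
#' @param lane_tau_s Mean-reversion time constant of the lateral-position
#'   process, seconds.
#' @param lane_base_innov,lane_gain Lane-position innovation scale:
#'   `base * (1 + gain * sigma(d))` cm per sample-sd.
#' @param calib_offsets_cm,calib_interval_s Fixation-target offsets and
#'   per-target dwell for EOG calibration blocks.
#' @param viewing_distance_cm Eye-to-display distance, cm.
#' @param calib_noise_uv EOG noise during calibration, microvolts.
#' @param reference_s Length of the alert-state pupil reference recording, s.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_participants = 17,
                       n_sessions = 8,
                       trials_per_session = 3,
                       trial_s = 300,
                       gap_s = 60,
                       fs_eog = 1000, fs_eeg = 1000, fs_pupil = 60,
                       fs_lane = 10,
                       intercept_mean = -1.0, intercept_sd = 0.4,
                       session_step = 0.5, post_lunch_reset = 0.3,
                       trial_drift = 0.3,
                       ar_phi = 0.9, ar_sd = 0.3,
                       n_raters = 3,
                       rater_bias_sd = 0.3, rater_noise_sd = 0.4,
                       ord_coupling = 1, kss_coupling = 1,
                       kss_noise_sd = 0.5,
                       sem_base_rate = 0.5, sem_gain = 6,
                       sem_speed_range = c(5, 25),
                       sem_excursion_range = c(6, 20),
                       saccade_rate = 20, saccade_speed = 400,
                       saccade_amp_range = c(2, 15),
                       volts_per_degree_range = c(8, 20),
                       eog_noise_uv = 3,
                       pupil_base_mean = 7, pupil_base_sd = 0.5,
                       closure_base_rate = 0.3, closure_gain = 5,
                       closure_meanlog = log(0.8), closure_sdlog = 0.5,
                       closure_frac = 0.05, closure_invalid_prob = 0.5,
                       dropout_rate = 0.2, dropout_dur_range = c(0.03, 1.5),
                       pupil_noise_sd = 0.05,
                       eeg_bg_sd = 8,
                       alpha_gain = 20, theta_gain = 12,
                       burst_duty = 0.5,
                       eeg_noise_uv = 2,
                       artifact_rate = 0.3, artifact_amp_uv = 300,
                       artifact_dur_s = 0.2,
                       lane_tau_s = 20,
                       lane_base_innov = 1.7, lane_gain = 1.5,
                       calib_offsets_cm = c(0, 30, -30),
                       calib_interval_s = 3,
                       viewing_distance_cm = 91.1,
                       calib_noise_uv = 5,
                       reference_s = 120) {
  cfg <- as.list(environment())
  stopifnot(n_participants >= 2, n_sessions >= 1, trials_per_session >= 1,
            ar_phi >= 0, ar_phi < 1, ar_sd >= 0,
            sem_base_rate >= 0, sem_gain >= 0,
            closure_base_rate >= 0, closure_gain >= 0,
            alpha_gain >= 0, theta_gain >= 0, lane_gain >= 0)
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config: %d participants x %d sessions x %d trials of %g s>\n",
              x$n_participants, x$n_sessions, x$trials_per_session, x$trial_s))
  invisible(x)
}

.str_hash <- function(x) {
  h <- 0
  for (c in utf8ToInt(x)) h <- (h * 131 + c) %% 1000003
  h
}

# Deterministic sub-seed for a participant/stage/session stream, < 2^31.
.sub_seed <- function(seed, ...) {
  k <- c(...)
  s <- as.double(seed %% 2147483647L)
  for (v in k) s <- (s * 69069 + v * 7919 + 1) %% 2147483647
  as.integer(s)
}

.session_offset <- function(s, config) {
  ifelse(s <= 3, config$session_step * (s - 1),
         config$post_lunch_reset + config$session_step * (s - 4))
}

#' Simulate latent drowsiness trajectories
#'
#' Per participant, a 1-Hz latent drowsiness level over every trial:
#' participant intercept + between-session trend with a lunch-break reset +
#' within-session linear drift + stationary AR(1) noise.  Higher values mean
#' drowsier; the logistic `sigma(d)` maps the latent onto the unit interval
#' wherever a bounded quantity is needed.  Deterministic given
#' `(config, seed)`.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A list of class `"latent_cohort"`: per participant a list with
#'   `participant_id`, `intercept`, `volts_per_degree`, `pupil_base_mm`,
#'   `fine` (list over sessions of `trial_s x trials_per_session` matrices of
#'   the 1-Hz latent) and `trial_d` (sessions x trials matrix of trial-mean
#'   latent).
#' @export
simulate_latent <- function(config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_participants < 2) stop("need >= 2 participants")
  set.seed(.sub_seed(seed, 0))
  n <- config$n_participants
  ids <- sprintf("sub%02d", seq_len(n))
  intercepts <- stats::rnorm(n, config$intercept_mean, config$intercept_sd)
  vpd <- stats::runif(n, config$volts_per_degree_range[1],
                      config$volts_per_degree_range[2])
  pup <- stats::rnorm(n, config$pupil_base_mean, config$pupil_base_sd)
  innov_sd <- config$ar_sd * sqrt(1 - config$ar_phi^2)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(.sub_seed(seed, 1, i))
    fine <- vector("list", config$n_sessions)
    trial_d <- matrix(NA_real_, config$n_sessions, config$trials_per_session)
    for (s in seq_len(config$n_sessions)) {
      npts <- config$trial_s * config$trials_per_session
      e <- stats::rnorm(npts, 0, innov_sd)
      noise <- as.numeric(stats::filter(e, config$ar_phi,
                                        method = "recursive",
                                        init = stats::rnorm(1, 0, config$ar_sd)))
      m <- matrix(NA_real_, config$trial_s, config$trials_per_session)
      for (j in seq_len(config$trials_per_session)) {
        tt <- seq_len(config$trial_s) / config$trial_s   # (0, 1]
        drift <- config$trial_drift * ((j - 1) + tt)
        base <- intercepts[i] + .session_offset(s, config) + drift
        m[, j] <- base + noise[(j - 1) * config$trial_s + seq_len(config$trial_s)]
      }
      fine[[s]] <- m
      trial_d[s, ] <- colMeans(m)
    }
    out[[i]] <- list(participant_id = ids[i], intercept = intercepts[i],
                     volts_per_degree = vpd[i], pupil_base_mm = pup[i],
                     fine = fine, trial_d = trial_d)
  }
  structure(out, class = "latent_cohort", config = config, seed = seed)
}

# Sequential marked point process on [0, duration): exponential gaps at
# `rate` events/s, durations from dur_fun(n).  Events may overrun `duration`.
.place_events <- function(duration, rate, dur_fun) {
  if (rate <= 0) return(data.frame(start = numeric(0), dur = numeric(0)))
  start <- dur <- numeric(0)
  t <- stats::rexp(1, rate)
  while (t < duration) {
    d <- dur_fun(1)
    start <- c(start, t); dur <- c(dur, d)
    t <- t + d + stats::rexp(1, rate)
  }
  data.frame(start = start, dur = dur)
}

#' Simulate one participant-session recording
#'
#' Builds the four signal channels and the KSS prompt events of one session
#' from the participant's latent trajectory:
#' \itemize{
#'   \item horizontal EOG: sparse fast saccades plus slow-eye-movement drift
#'     episodes whose rate grows with `sigma(d)`, scaled to microvolts by the
#'     participant's volts-per-degree constant, plus white noise;
#'   \item pupil diameter: baseline with slow fluctuation, closure episodes
#'     (rate growing with `sigma(d)`) during which the diameter collapses and
#'     tracking is lost with probability `closure_invalid_prob`, plus
#'     occasional unrelated dropouts;
#'   \item EEG: autoregressive background plus 10-Hz alpha and 6-Hz theta
#'     bursts whose amplitudes grow with `sigma(d)`, plus rare high-amplitude
#'     movement artifacts;
#'   \item lateral lane position: mean-reverting random walk whose innovation
#'     scale grows with `sigma(d)`;
#'   \item KSS response at each prompt:
#'     `clamp(round(1 + 8 * sigma(kss_coupling * d + noise)), 1, 9)`.
#' }
#'
#' @param lat One participant element of [simulate_latent()].
#' @param session Session index.
#' @param config A [sim_config()].
#' @param seed Integer seed (sub-streamed per participant and session, so any
#'   session can be regenerated independently).
#' @return A [recording()].
#' @export
simulate_recording <- function(lat, session, config = sim_config(), seed = 1) {
  J <- config$trials_per_session
  slot <- config$trial_s + config$gap_s
  sess_s <- J * slot
  sig_trial <- stats::plogis(lat$trial_d[session, ])
  # per-second logistic latent over the session (gaps carry the last value)
  sig_sec <- numeric(sess_s)
  for (j in seq_len(J)) {
    w <- (j - 1) * slot + seq_len(config$trial_s)
    sig_sec[w] <- stats::plogis(lat$fine[[session]][, j])
    sig_sec[(j - 1) * slot + config$trial_s + seq_len(config$gap_s)] <-
      sig_sec[(j - 1) * slot + config$trial_s]
  }
  set.seed(.sub_seed(seed, 2, session, .str_hash(lat$participant_id)))

  ## --- EOG -------------------------------------------------------------
  fs <- config$fs_eog
  n <- sess_s * fs
  vel <- numeric(n)
  a_cur <- 0
  for (j in seq_len(J)) {
    off <- (j - 1) * slot
    sem_rate <- (config$sem_base_rate + config$sem_gain * sig_trial[j]) / 60
    sac_rate <- config$saccade_rate / 60
    tot <- sem_rate + sac_rate
    if (tot <= 0) next
    t <- stats::rexp(1, tot)
    while (t < config$trial_s) {
      is_sem <- stats::runif(1) < sem_rate / tot
      if (is_sem) {
        speed <- stats::runif(1, config$sem_speed_range[1],
                              config$sem_speed_range[2])
        amp <- stats::runif(1, config$sem_excursion_range[1],
                            config$sem_excursion_range[2])
      } else {
        speed <- config$saccade_speed
        amp <- stats::runif(1, config$saccade_amp_range[1],
                            config$saccade_amp_range[2])
      }
      dur <- amp / speed
      dir <- if (abs(a_cur) > 8) -sign(a_cur) else sample(c(-1, 1), 1)
      i1 <- round((off + t) * fs) + 1L
      i2 <- min(round((off + t + dur) * fs), n)
      if (i1 <= n && i2 >= i1) {
        vel[i1:i2] <- dir * speed
        a_cur <- a_cur + dir * speed * (i2 - i1 + 1L) / fs
      }
      t <- t + dur + stats::rexp(1, tot)
    }
  }
  angle <- cumsum(vel) / fs
  eog <- channel("eog_h", fs,
                 angle * lat$volts_per_degree +
                   stats::rnorm(n, 0, config$eog_noise_uv))

  ## --- EEG -------------------------------------------------------------
  fs <- config$fs_eeg
  n <- sess_s * fs
  innov <- stats::rnorm(n)
  bg <- as.numeric(stats::filter(innov, 0.99, method = "recursive"))
  bg <- bg / sqrt(1 / (1 - 0.99^2)) * config$eeg_bg_sd
  t_ax <- seq_len(n) / fs
  blk <- pmin(floor(t_ax / 2) + 1, ceiling(sess_s / 2))
  n_blk <- max(blk)
  on_a <- stats::runif(n_blk) < config$burst_duty
  on_t <- stats::runif(n_blk) < config$burst_duty
  sig_t <- sig_sec[pmin(ceiling(t_ax), sess_s)]
  env_a <- config$alpha_gain * sig_t * on_a[blk]
  env_t <- config$theta_gain * sig_t * on_t[blk]
  # suppress bursts outside trials (no task engagement during KSS response)
  in_trial <- ((t_ax - 1e-9) %% slot) < config$trial_s
  eegv <- bg +
    env_a * in_trial * sin(2 * pi * 10 * t_ax + stats::runif(1, 0, 2 * pi)) +
    env_t * in_trial * sin(2 * pi * 6 * t_ax + stats::runif(1, 0, 2 * pi)) +
    stats::rnorm(n, 0, config$eeg_noise_uv)
  art <- .place_events(sess_s, config$artifact_rate / 60,
                       function(k) rep(config$artifact_dur_s, k))
  for (e in seq_len(nrow(art))) {
    i1 <- round(art$start[e] * fs) + 1L
    i2 <- min(round((art$start[e] + art$dur[e]) * fs), n)
    eegv[i1:i2] <- eegv[i1:i2] + config$artifact_amp_uv
  }
  eeg <- channel("eeg_c3", fs, eegv)

  ## --- pupil -----------------------------------------------------------
  fs <- config$fs_pupil
  n <- sess_s * fs
  t_ax <- seq_len(n) / fs
  diam <- lat$pupil_base_mm +
    0.2 * sin(2 * pi * 0.05 * t_ax + stats::runif(1, 0, 2 * pi)) +
    stats::rnorm(n, 0, config$pupil_noise_sd)
  valid <- rep(TRUE, n)
  for (j in seq_len(J)) {
    off <- (j - 1) * slot
    rate <- (config$closure_base_rate + config$closure_gain * sig_trial[j]) / 60
    cl <- .place_events(config$trial_s, rate, function(k) {
      stats::rlnorm(k, config$closure_meanlog, config$closure_sdlog)
    })
    for (e in seq_len(nrow(cl))) {
      i1 <- round((off + cl$start[e]) * fs) + 1L
      i2 <- min(round((off + cl$start[e] + cl$dur[e]) * fs), n)
      if (i1 > n || i2 < i1) next
      diam[i1:i2] <- config$closure_frac * lat$pupil_base_mm +
        stats::rnorm(i2 - i1 + 1L, 0, config$pupil_noise_sd / 2)
      valid[i1:i2] <- stats::runif(i2 - i1 + 1L) >= config$closure_invalid_prob
    }
  }
  drp <- .place_events(sess_s, config$dropout_rate / 60, function(k) {
    stats::runif(k, config$dropout_dur_range[1], config$dropout_dur_range[2])
  })
  for (e in seq_len(nrow(drp))) {
    i1 <- round(drp$start[e] * fs) + 1L
    i2 <- min(round((drp$start[e] + drp$dur[e]) * fs), n)
    if (i1 > n || i2 < i1) next
    valid[i1:i2] <- FALSE
  }
  pupil <- channel("pupil_diameter", fs, diam, validity = valid)

  ## --- lane position ---------------------------------------------------
  fs <- config$fs_lane
  n <- sess_s * fs
  phi <- exp(-1 / (fs * config$lane_tau_s))
  innov_sd <- numeric(n)
  for (j in seq_len(J)) {
    w <- ((j - 1) * slot * fs + 1L):(j * slot * fs)
    innov_sd[w] <- config$lane_base_innov *
      (1 + config$lane_gain * sig_trial[j])
  }
  lane <- channel("lane_position", fs,
                  as.numeric(stats::filter(stats::rnorm(n, 0, innov_sd), phi,
                                           method = "recursive")))

  ## --- KSS prompts ------------------------------------------------------
  kss <- pmin(pmax(round(1 + 8 * stats::plogis(
    config$kss_coupling * lat$trial_d[session, ] +
      stats::rnorm(J, 0, config$kss_noise_sd))), 1), 9)
  prompts <- data.frame(time = (seq_len(J) - 1) * slot + config$trial_s,
                        response = as.integer(kss))

  recording(lat$participant_id, session,
            list(eog, eeg, pupil, lane), prompts)
}

#' Simulate per-rater ORD labels for one session
#'
#' Each rater scores every consecutive 5-s segment of each trial:
#' `clamp(round(1 + 4 * sigma(ord_coupling * d_seg + bias_r + noise)), 1, 5)`
#' where `d_seg` is the segment-mean latent, `bias_r` is the rater's fixed
#' bias and the noise is drawn per rater and segment.
#'
#' @param lat One participant element of [simulate_latent()].
#' @param session Session index.
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param biases Optional numeric vector of per-rater biases (drawn once per
#'   cohort); defaults to fresh draws from `N(0, rater_bias_sd)`.
#' @return A list with one `segments x raters` integer matrix per trial.
#' @export
simulate_raters <- function(lat, session, config = sim_config(), seed = 1,
                            biases = NULL) {
  set.seed(.sub_seed(seed, 3, session, .str_hash(lat$participant_id)))
  if (is.null(biases)) {
    biases <- stats::rnorm(config$n_raters, 0, config$rater_bias_sd)
  }
  n_seg <- config$trial_s %/% 5L
  lapply(seq_len(config$trials_per_session), function(j) {
    d_seg <- colMeans(matrix(lat$fine[[session]][, j], nrow = 5L))
    m <- vapply(seq_len(config$n_raters), function(r) {
      x <- config$ord_coupling * d_seg + biases[r] +
        stats::rnorm(n_seg, 0, config$rater_noise_sd)
      as.integer(pmin(pmax(round(1 + 4 * stats::plogis(x)), 1), 5))
    }, integer(n_seg))
    colnames(m) <- paste0("rater", seq_len(config$n_raters))
    m
  })
}

#' Simulate an EOG calibration block
#'
#' The participant fixates each configured target for `calib_interval_s`
#' seconds; the EOG voltage is the target angle times the participant's
#' volts-per-degree constant plus noise.
#'
#' @inheritParams simulate_raters
#' @param block 1 for the pre-session-1 block, 2 for the pre-session-4 block.
#' @return A list with `eog` (a [channel()]), `schedule` (`data.frame` of
#'   `start_s`, `end_s`, `offset_cm`) and `viewing_distance_cm`.
#' @export
simulate_calibration <- function(lat, block = 1, config = sim_config(),
                                 seed = 1) {
  set.seed(.sub_seed(seed, 4, block, .str_hash(lat$participant_id)))
  offs <- config$calib_offsets_cm
  k <- length(offs)
  iv <- config$calib_interval_s
  schedule <- data.frame(start_s = (seq_len(k) - 1) * iv,
                         end_s = seq_len(k) * iv, offset_cm = offs)
  theta <- atan(offs / config$viewing_distance_cm) * 180 / pi
  fs <- config$fs_eog
  v <- rep(theta, each = iv * fs) * lat$volts_per_degree +
    stats::rnorm(k * iv * fs, 0, config$calib_noise_uv)
  list(eog = channel("eog_h", fs, v), schedule = schedule,
       viewing_distance_cm = config$viewing_distance_cm)
}

#' Simulate the alert-state pupil reference recording
#'
#' The vigilance-task block with the participant's lowest KSS, used only to
#' estimate the baseline maximum pupil diameter: baseline plus slow
#' fluctuation and noise, no closures.
#'
#' @inheritParams simulate_raters
#' @return A pupil-diameter [channel()].
#' @export
simulate_pupil_reference <- function(lat, config = sim_config(), seed = 1) {
  set.seed(.sub_seed(seed, 5, .str_hash(lat$participant_id)))
  fs <- config$fs_pupil
  n <- config$reference_s * fs
  t_ax <- seq_len(n) / fs
  channel("pupil_diameter", fs,
          lat$pupil_base_mm + 0.15 * sin(2 * pi * 0.05 * t_ax) +
            stats::rnorm(n, 0, config$pupil_noise_sd),
          validity = rep(TRUE, n))
}

#' Simulate a complete cohort of recordings
#'
#' Materialises every participant-session [recording()], the per-trial rater
#' label matrices, the calibration blocks and the pupil reference.  Intended
#' for small configurations (tests, demonstrations); for the full 17 x 8 x 3
#' design use the streaming [extract_cohort()], which never holds more than
#' one session in memory.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A list of class `"sim_cohort"`: `latent`, `rater_biases`, and per
#'   participant a list with `recordings` (by session), `ratings` (by session,
#'   then trial), `calibrations` (blocks 1 and 2), `pupil_reference`.
#' @export
simulate_cohort <- function(config = sim_config(), seed = 1) {
  lat <- simulate_latent(config, seed)
  set.seed(.sub_seed(seed, 6))
  biases <- stats::rnorm(config$n_raters, 0, config$rater_bias_sd)
  participants <- lapply(lat, function(lp) {
    list(participant_id = lp$participant_id,
         recordings = lapply(seq_len(config$n_sessions), function(s) {
           simulate_recording(lp, s, config, seed)
         }),
         ratings = lapply(seq_len(config$n_sessions), function(s) {
           simulate_raters(lp, s, config, seed, biases)
         }),
         calibrations = lapply(1:2, function(b) {
           simulate_calibration(lp, b, config, seed)
         }),
         pupil_reference = simulate_pupil_reference(lp, config, seed))
  })
  structure(list(latent = lat, rater_biases = biases,
                 participants = participants, config = config, seed = seed),
            class = "sim_cohort")
}

#' Simulate a trial-level measure table directly
#'
#' The generator's trial-level layer: draws the seven measures per trial
#' straight from the latent process and the configured coupling gains,
#' skipping waveform synthesis and extraction.  Each measure follows the
#' same construction its waveform counterpart induces (episode-rate models
#' for %SEM and PERCLOS, burst-power model for the EEG bands, stationary-sd
#' model for SDLP, discretised logistic responses for KSS and ORD), so the
#' table has the statistical structure of an extracted cohort at a fraction
#' of the cost.  Used for fast statistical checks, e.g. type-I-error
#' calibration with all couplings set to zero.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return A measure table (see [assemble_measure_table()]).
#' @export
#' @examples
#' tab <- simulate_measure_table(sim_config(n_participants = 4), seed = 7)
#' nrow(tab)  # 4 * 8 * 3
simulate_measure_table <- function(config = sim_config(), seed = 1) {
  lat <- simulate_latent(config, seed)
  set.seed(.sub_seed(seed, 7))
  biases <- stats::rnorm(config$n_raters, 0, config$rater_bias_sd)
  phi <- exp(-1 / (config$fs_lane * config$lane_tau_s))
  lane_sd_mult <- 1 / sqrt(1 - phi^2)
  rows <- list()
  for (lp in lat) {
    for (s in seq_len(config$n_sessions)) {
      for (j in seq_len(config$trials_per_session)) {
        d <- lp$trial_d[s, j]
        sg <- stats::plogis(d)
        d_seg <- colMeans(matrix(lp$fine[[s]][, j], nrow = 5L))
        n_seg <- length(d_seg)
        ord <- mean(vapply(seq_len(config$n_raters), function(r) {
          x <- config$ord_coupling * d_seg + biases[r] +
            stats::rnorm(n_seg, 0, config$rater_noise_sd)
          mean(pmin(pmax(round(1 + 4 * stats::plogis(x)), 1), 5))
        }, numeric(1)))
        kss <- pmin(pmax(round(1 + 8 * stats::plogis(
          config$kss_coupling * d + stats::rnorm(1, 0, config$kss_noise_sd))),
          1), 9)
        sem_rate <- (config$sem_base_rate + config$sem_gain * sg) / 60
        n_sem <- stats::rpois(1, sem_rate * config$trial_s)
        sem_pct <- if (n_sem > 0) {
          dur <- stats::runif(n_sem, config$sem_excursion_range[1],
                              config$sem_excursion_range[2]) /
            stats::runif(n_sem, config$sem_speed_range[1],
                         config$sem_speed_range[2])
          min(100 * sum(dur) / config$trial_s, 100)
        } else 0
        cl_rate <- (config$closure_base_rate + config$closure_gain * sg) / 60
        n_cl <- stats::rpois(1, cl_rate * config$trial_s)
        perclos_pct <- if (n_cl > 0) {
          dur <- stats::rlnorm(n_cl, config$closure_meanlog,
                               config$closure_sdlog)
          min(100 * sum(dur[dur > 0.4]) / config$trial_s, 100)
        } else 0
        sdlp_cm <- config$lane_base_innov * (1 + config$lane_gain * sg) *
          lane_sd_mult * exp(stats::rnorm(1, 0, 0.15))
        sig_fine <- stats::plogis(lp$fine[[s]][, j])
        duty_a <- stats::rbinom(1, 150, config$burst_duty) / 150
        duty_t <- stats::rbinom(1, 150, config$burst_duty) / 150
        alpha <- (2.5 + duty_a * mean((config$alpha_gain * sig_fine)^2) / 2) *
          exp(stats::rnorm(1, 0, 0.1))
        theta <- (6.5 + duty_t * mean((config$theta_gain * sig_fine)^2) / 2) *
          exp(stats::rnorm(1, 0, 0.1))
        rows[[length(rows) + 1L]] <- data.frame(
          participant_id = lp$participant_id, session = s, trial = j,
          ord_mean = ord, kss = kss, sdlp_cm = sdlp_cm,
          perclos_pct = perclos_pct, sem_pct = sem_pct,
          eeg_alpha_power = alpha, eeg_theta_power = theta,
          stringsAsFactors = FALSE)
      }
    }
  }
  assemble_measure_table(do.call(rbind, rows))
}
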