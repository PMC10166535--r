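small_cfg <- function(...) sim_config(n_participants = 2, n_sessions = 2, ...)

test_that("latent trajectories are deterministic and shaped by the design", {
  cfg <- small_cfg()
  a <- simulate_latent(cfg, seed = 5)
  b <- simulate_latent(cfg, seed = 5)
  expect_identical(a, b)
  expect_length(a, 2L)
  expect_equal(dim(a[[1]]$trial_d), c(2, 3))
  expect_equal(dim(a[[1]]$fine[[1]]), c(300, 3))
  # per-trial level equals the mean of the fine-scale latent
  expect_equal(a[[1]]$trial_d[1, 2], mean(a[[1]]$fine[[1]][, 2]))
  expect_error(simulate_latent(sim_config(n_participants = 2)[
    names(sim_config())] , 5))  # stripped class rejected
})

test_that("degenerate variance collapses the latent to its deterministic part", {
  cfg <- small_cfg(intercept_mean = 0.3, intercept_sd = 0, ar_sd = 0,
                   session_step = 0, post_lunch_reset = 0, trial_drift = 0)
  lat <- simulate_latent(cfg, seed = 1)
  expect_true(all(abs(unlist(lat[[1]]$fine) - 0.3) < 1e-12))

  # positive drift, zero noise: strictly increasing within each session
  cfg2 <- small_cfg(intercept_sd = 0, ar_sd = 0, trial_drift = 0.4)
  lat2 <- simulate_latent(cfg2, seed = 1)
  for (s in 1:2) expect_true(all(diff(lat2[[1]]$trial_d[s, ]) > 0))
  expect_true(all(diff(as.vector(lat2[[1]]$fine[[1]])) > 0))
})

test_that("the lunch break resets the between-session build-up", {
  cfg <- sim_config(n_participants = 2, intercept_sd = 0, ar_sd = 0,
                    trial_drift = 0)
  lat <- simulate_latent(cfg, seed = 1)
  d1 <- lat[[1]]$trial_d[, 1]
  expect_true(all(diff(d1[1:3]) > 0))   # builds up before lunch
  expect_lt(d1[4], d1[3])               # post-lunch reset
  expect_true(all(diff(d1[4:8]) > 0))   # builds up again after lunch
})

test_that("recordings are deterministic and carry the design structure", {
  cfg <- small_cfg()
  lat <- simulate_latent(cfg, seed = 2)
  r1 <- simulate_recording(lat[[1]], 1, cfg, seed = 2)
  r2 <- simulate_recording(lat[[1]], 1, cfg, seed = 2)
  expect_identical(r1, r2)
  expect_setequal(names(r1$channels),
                  c("eog_h", "eeg_c3", "pupil_diameter", "lane_position"))
  expect_equal(nrow(r1$kss_prompts), 3L)
  expect_equal(r1$kss_prompts$time, c(300, 660, 1020))
  expect_true(all(r1$kss_prompts$response %in% 1:9))
  expect_equal(length(r1$channels$eog_h$values), 3 * 360 * 1000)
  expect_equal(length(r1$channels$pupil_diameter$values), 3 * 360 * 60)
})

test_that("rater scores clamp at the scale limits for extreme latents", {
  cfg <- small_cfg(rater_bias_sd = 0, rater_noise_sd = 0)
  lat <- simulate_latent(cfg, seed = 3)
  lat[[1]]$fine[[1]][] <- -50   # far below scale
  r_low <- simulate_raters(lat[[1]], 1, cfg, seed = 3)
  expect_true(all(r_low[[1]] == 1L))
  lat[[1]]$fine[[1]][] <- 50    # far above scale
  r_hi <- simulate_raters(lat[[1]], 1, cfg, seed = 3)
  expect_true(all(r_hi[[1]] == 5L))
  expect_equal(dim(r_hi[[1]]), c(60, 3))
})

test_that("zero coupling decorrelates measures from the latent state", {
  cfg0 <- sim_config(n_participants = 2, n_sessions = 8,
                     sem_gain = 0, closure_gain = 0, alpha_gain = 0,
                     theta_gain = 0, lane_gain = 0,
                     ord_coupling = 0, kss_coupling = 0)
  mean_r <- colMeans(do.call(rbind, lapply(1:20, function(s) {
    lat <- simulate_latent(cfg0, seed = s)
    tab <- simulate_measure_table(cfg0, seed = s)
    d <- as.vector(t(lat[[1]]$trial_d))
    p1 <- tab[tab$participant_id == "sub01", ]
    vapply(c("ord_mean", "sdlp_cm", "sem_pct", "eeg_alpha_power"),
           function(m) cor(d, p1[[m]]), numeric(1))
  })))
  expect_true(all(abs(mean_r) < 0.1))
})

test_that("positive coupling makes every measure rise with the latent state", {
  cfg <- sim_config(n_participants = 2)
  ms <- c("ord_mean", "kss", "sdlp_cm", "perclos_pct", "sem_pct",
          "eeg_alpha_power", "eeg_theta_power")
  mean_r <- colMeans(do.call(rbind, lapply(1:20, function(s) {
    lat <- simulate_latent(cfg, seed = s)
    tab <- simulate_measure_table(cfg, seed = s)
    d <- as.vector(t(lat[[1]]$trial_d))
    p1 <- tab[tab$participant_id == "sub01", ]
    vapply(ms, function(m) cor(d, p1[[m]]), numeric(1))
  })))
  expect_true(all(mean_r > 0.3))
})

test_that("a strong SEM gain raises late-session %SEM above early-session %SEM", {
  cfg <- sim_config(n_participants = 2, intercept_mean = -2, intercept_sd = 0,
                    session_step = 0.6, trial_drift = 0.3, sem_gain = 8)
  diffs <- vapply(1:20, function(s) {
    tab <- simulate_measure_table(cfg, seed = s)
    p1 <- tab[tab$participant_id == "sub01", ]
    mean(p1$sem_pct[p1$trial_order == 24]) -
      mean(p1$sem_pct[p1$trial_order == 1])
  }, numeric(1))
  expect_gt(mean(diffs), 0)
  expect_gt(mean(diffs > 0), 0.8)
})

test_that("measure-level tables are deterministic and in valid ranges", {
  cfg <- small_cfg()
  t1 <- simulate_measure_table(cfg, seed = 9)
  t2 <- simulate_measure_table(cfg, seed = 9)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), 2 * 2 * 3)
  expect_true(all(t1$ord_mean >= 1 & t1$ord_mean <= 5))
  expect_true(all(t1$kss %in% 1:9))
  expect_true(all(t1$perclos_pct >= 0 & t1$perclos_pct <= 100))
  expect_true(all(t1$eeg_alpha_power > 0))
})

test_that("waveform extraction tracks the latent on a full-length participant", {
  # one participant, all 8 sessions through the signal pipeline: the
  # extracted measures must correlate positively with the latent state
  cfg <- sim_config(n_participants = 2)
  lat <- simulate_latent(cfg, seed = 6)
  lp <- lat[[1]]
  cb <- simulate_calibration(lp, 1, cfg, seed = 6)
  cal <- calibrate_eog(cb$eog, cb$schedule, cb$viewing_distance_cm)
  base <- baseline_pupil_max(simulate_pupil_reference(lp, cfg, seed = 6))
  rows <- do.call(rbind, lapply(1:8, function(s) {
    rec <- simulate_recording(lp, s, cfg, seed = 6)
    extract_measures(rec, cal, base, simulate_raters(lp, s, cfg, seed = 6))
  }))
  d <- as.vector(t(lp$trial_d))
  for (m in c("ord_mean", "sdlp_cm", "perclos_pct", "sem_pct",
              "eeg_alpha_power", "eeg_theta_power")) {
    expect_gt(cor(d, rows[[m]]), 0.15)
  }
  expect_gt(cor(d, rows$kss, method = "spearman"), 0.15)
})

test_that("a materialised cohort bundles recordings, ratings and references", {
  cfg <- sim_config(n_participants = 2, n_sessions = 1)
  coh <- simulate_cohort(cfg, seed = 2)
  expect_s3_class(coh, "sim_cohort")
  expect_length(coh$participants, 2L)
  p <- coh$participants[[1]]
  expect_length(p$recordings, 1L)
  expect_s3_class(p$recordings[[1]], "recording")
  expect_length(p$ratings[[1]], 3L)          # one matrix per trial
  expect_equal(dim(p$ratings[[1]][[1]]), c(60, 3))
  expect_length(p$calibrations, 2L)          # pre-S1 and pre-S4 blocks
  expect_s3_class(p$pupil_reference, "channel")
  # the embedded latent equals a standalone draw at the same seed
  expect_identical(coh$latent, simulate_latent(cfg, seed = 2))
})

test_that("configuration objects print their key constants", {
  expect_output(print(sim_config()), "17 participants")
  expect_output(print(analysis_config()), "30 deg/s")
  expect_output(print(channel("eog_h", 1000, 1:5)), "5 samples")
})
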