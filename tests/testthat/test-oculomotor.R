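make_cal <- function(vpd = 12) {
  structure(list(volts_per_degree = vpd,
                 targets = data.frame(theta_deg = c(-18, 0, 18),
                                      median_uv = vpd * c(-18, 0, 18)),
                 viewing_distance_cm = 91.1),
            class = "eog_calibration")
}

test_that("fixation targets map to the expected visual angles", {
  iv <- 2; fs <- 1000
  sched <- data.frame(start_s = c(0, 2, 4), end_s = c(2, 4, 6),
                      offset_cm = c(0, 30, -30))
  theta <- atan(sched$offset_cm / 91.1) * 180 / pi
  expect_equal(theta, c(0, 18.22, -18.22), tolerance = 1e-3)
  v <- rep(theta, each = iv * fs) * 12
  cal <- calibrate_eog(channel("eog_h", fs, v), sched, 91.1)
  expect_equal(cal$volts_per_degree, 12, tolerance = 1e-9)
})

test_that("calibration recovers the gain under noise and rejects degenerate input", {
  sched <- data.frame(start_s = c(0, 2, 4), end_s = c(2, 4, 6),
                      offset_cm = c(0, 30, -30))
  theta <- atan(sched$offset_cm / 91.1) * 180 / pi
  set.seed(42)
  est <- replicate(20, {
    v <- rep(theta, each = 2000) * 12 + rnorm(6000, 0, 5)
    calibrate_eog(channel("eog_h", 1000, v), sched, 91.1)$volts_per_degree
  })
  expect_true(all(abs(est - 12) < 0.5))

  expect_error(calibrate_eog(channel("eog_h", 1000, rnorm(6000)),
                             transform(sched, offset_cm = 10), 91.1),
               "distinct")
  flat <- rep(0.01 * theta, each = 2000)  # slope far below 1 uV/deg
  expect_error(calibrate_eog(channel("eog_h", 1000, flat), sched, 91.1),
               "implausible")
})

test_that("angle conversion scales by the gain and filters as designed", {
  cal <- make_cal(12)
  ch <- channel("eog_h", 1000, rep(120, 2000))
  expect_equal(mean(eog_to_angle(ch, cal)$values), 10, tolerance = 1e-6)

  t <- seq(0, 4 - 1e-3, by = 1e-3)
  passed <- eog_to_angle(channel("eog_h", 1000, sin(2 * pi * 1 * t)),
                         make_cal(1))
  expect_gt(max(abs(passed$values[1000:3000])), 0.95)
  blocked <- eog_to_angle(channel("eog_h", 1000, sin(2 * pi * 50 * t)),
                          make_cal(1))
  expect_lt(max(abs(blocked$values[1000:3000])), 10^(-20 / 20))
})

test_that("SEM detector accepts slow large drifts and rejects fast or small ones", {
  fs <- 1000
  # linear sweep 0 -> 20 deg over 1 s: one episode of ~20 deg at 20 deg/s
  a <- c(rep(0, 500), seq(0, 20, length.out = 1001), rep(20, 500))
  ep <- detect_sem(channel("gaze_angle", fs, a))
  expect_equal(nrow(ep), 1L)
  expect_equal(ep$net_displacement_deg, 20, tolerance = 0.5)
  expect_lt(ep$mean_speed_deg_s, 30)
  expect_equal(ep$end_s - ep$start_s, 2, tolerance = 0.1)  # run spans fixations

  # 10-deg step completed in 25 ms: 400 deg/s, no episode from the step
  a2 <- c(rep(0, 1000), seq(0, 10, length.out = 26), rep(10, 1000))
  ep2 <- detect_sem(channel("gaze_angle", fs, a2))
  expect_equal(nrow(ep2), 0L)

  # 2-deg slow drift: criterion 2 fails
  a3 <- c(rep(0, 500), seq(0, 2, length.out = 1001), rep(2, 500))
  expect_equal(nrow(detect_sem(channel("gaze_angle", fs, a3))), 0L)

  # too-short series: empty with diagnostic
  expect_warning(ep4 <- detect_sem(channel("gaze_angle", fs, c(0, 1))),
                 "shorter")
  expect_equal(nrow(ep4), 0L)
})

test_that("detector is equivariant under joint voltage/gain rescaling", {
  set.seed(7)
  fs <- 200
  a <- cumsum(rnorm(2000, 0, 0.05)) + 10 * sin(seq(0, 3 * pi, length.out = 2000))
  e1 <- detect_sem(channel("gaze_angle", fs, a))
  # doubling voltage and volts-per-degree leaves the angle series unchanged
  cal2 <- structure(list(volts_per_degree = 24), class = "eog_calibration")
  cal1 <- structure(list(volts_per_degree = 12), class = "eog_calibration")
  v <- a * 12
  ang1 <- eog_to_angle(channel("eog_h", fs, v), cal1)
  ang2 <- eog_to_angle(channel("eog_h", fs, 2 * v), cal2)
  expect_equal(ang1$values, ang2$values, tolerance = 1e-12)
  expect_equal(detect_sem(ang1), detect_sem(ang2))
  expect_true(is.data.frame(e1))
})

test_that("percent SEM clips to the trial window and is monotone", {
  eps <- data.frame(start_s = c(10, 50), end_s = c(25, 65),
                    net_displacement_deg = c(8, -7),
                    mean_speed_deg_s = c(10, 12))
  expect_equal(percent_sem(eps, 0, 300), 10)
  expect_equal(percent_sem(eps[0, ], 0, 300), 0)
  # boundary-spanning episode: only the inside portion counts
  cross <- data.frame(start_s = 290, end_s = 310,
                      net_displacement_deg = 8, mean_speed_deg_s = 10)
  expect_equal(percent_sem(cross, 0, 300), 100 * 10 / 300)
  # adding an episode never decreases the value
  expect_gte(percent_sem(rbind(eps, cross), 0, 300), percent_sem(eps, 0, 300))
  # overlap violates the detector contract
  bad <- data.frame(start_s = c(0, 5), end_s = c(10, 15),
                    net_displacement_deg = c(6, 6), mean_speed_deg_s = c(5, 5))
  expect_error(percent_sem(bad, 0, 300), "overlap")
})

test_that("detector agrees with the brute-force oracle on random short traces", {
  set.seed(11)
  for (case in 1:25) {
    fs <- sample(c(100, 200, 500), 1)
    dur <- runif(1, 2, 8)
    n <- round(fs * dur)
    a <- cumsum(rnorm(n, 0, runif(1, 0.01, 0.3))) +
      runif(1, 5, 25) * sin(2 * pi * runif(1, 0.1, 0.5) * seq_len(n) / fs)
    got <- detect_sem(channel("gaze_angle", fs, a))
    want <- oracle_sem(a, fs)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(nrow(got), nrow(want))
      expect_equal(got$start_s, want$start_s, tolerance = 1e-9)
      expect_equal(got$end_s, want$end_s, tolerance = 1e-9)
      expect_equal(got$net_displacement_deg, want$net_displacement_deg,
                   tolerance = 1e-9)
    }
  }
})
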