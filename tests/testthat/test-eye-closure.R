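test_that("baseline is the histogram mode with ties toward larger diameters", {
  fs <- 60
  v <- c(rep(7.9, 80 * fs), rep(6.5, 40 * fs))
  base <- baseline_pupil_max(channel("pupil_diameter", fs, v))
  expect_lt(abs(base$max_diameter - 7.9), 0.051)  # within half a 0.1-mm bin

  v2 <- c(rep(6.0, 40 * fs), rep(8.0, 40 * fs))
  base2 <- baseline_pupil_max(channel("pupil_diameter", fs, v2))
  expect_gt(base2$max_diameter, 7.9)  # tie broken toward the larger mode

  expect_error(baseline_pupil_max(channel("pupil_diameter", fs, rep(7, 100))),
               "60 s")
})

test_that("baseline mode tracks the centre of a unimodal diameter distribution", {
  set.seed(21)
  est <- replicate(20, {
    v <- rnorm(90 * 60, 7, 0.3)
    baseline_pupil_max(channel("pupil_diameter", 60, v))$max_diameter
  })
  expect_true(all(abs(est - 7) < 0.25))
})

test_that("PERCLOS counts only sub-threshold runs longer than 400 ms", {
  fs <- 60
  base <- structure(list(max_diameter = 8, bin_width = 0.1),
                    class = "pupil_baseline")
  # 1.2 s at 1.0 mm (threshold 1.6 mm) inside a 300-s window -> 0.4%
  ch <- make_pupil(fs, 300, base = 8,
                   dips = data.frame(start = 100, end = 101.2, level = 1.0))
  res <- perclos(ch, base, 0, 300)
  expect_equal(res$perclos_pct, 0.4, tolerance = 1e-6)
  expect_equal(nrow(res$episodes), 1L)

  # a 300-ms dip is below the duration rule
  ch2 <- make_pupil(fs, 300, base = 8,
                    dips = data.frame(start = 100, end = 100.3, level = 1.0))
  expect_equal(perclos(ch2, base, 0, 300)$perclos_pct, 0)

  # constant at baseline
  ch3 <- make_pupil(fs, 300, base = 8)
  expect_equal(perclos(ch3, base, 0, 300)$perclos_pct, 0)
})

test_that("tracking loss contiguous with closure counts as closed", {
  fs <- 60
  base <- structure(list(max_diameter = 8, bin_width = 0.1),
                    class = "pupil_baseline")
  # 0.5 s below threshold followed by 0.5 s of signal loss: one 1-s episode
  ch <- make_pupil(fs, 60, base = 8,
                   dips = data.frame(start = 10, end = 10.5, level = 1.0),
                   invalid = data.frame(start = 10.5, end = 11.0))
  res <- perclos(ch, base, 0, 60)
  expect_equal(res$perclos_pct, 100 * 1.0 / 60, tolerance = 0.01)

  # a short isolated dropout in open eyes is bridged, not counted
  ch2 <- make_pupil(fs, 60, base = 8,
                    invalid = data.frame(start = 20, end = 20.05))
  expect_equal(perclos(ch2, base, 0, 60)$perclos_pct, 0)

  # a long isolated dropout is excluded from the denominator
  ch3 <- make_pupil(fs, 60, base = 8,
                    dips = data.frame(start = 5, end = 6, level = 1.0),
                    invalid = data.frame(start = 30, end = 40))
  res3 <- perclos(ch3, base, 0, 60)
  expect_equal(res3$perclos_pct, 100 * 1 / 50, tolerance = 0.02)

  # mostly-lost trials give a missing value
  ch4 <- make_pupil(fs, 60, base = 8,
                    invalid = data.frame(start = 1, end = 59))
  expect_warning(res4 <- perclos(ch4, base, 0, 60), "tracking loss")
  expect_true(is.na(res4$perclos_pct))
})

test_that("PERCLOS matches the sample-wise oracle on random short traces", {
  set.seed(31)
  fs <- 60
  for (case in 1:25) {
    dur <- sample(5:10, 1)
    n <- fs * dur
    v <- 8 + rnorm(n, 0, 0.3)
    # random dips and dropouts
    for (k in seq_len(sample(1:4, 1))) {
      i <- sample(n - 40, 1); len <- sample(3:40, 1)
      v[i:(i + len)] <- runif(1, 0.2, 2.5)
    }
    ok <- runif(n) > 0.03
    ch <- channel("pupil_diameter", fs, v, validity = ok)
    base <- structure(list(max_diameter = 8, bin_width = 0.1),
                      class = "pupil_baseline")
    got <- suppressWarnings(perclos(ch, base, 0, dur)$perclos_pct)
    want <- oracle_perclos(v, ok, fs, 0.2 * 8, dur)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("PERCLOS is monotone in the threshold and scale invariant", {
  set.seed(41)
  fs <- 60
  v <- 8 - 6 * pmax(sin(seq(0, 8 * pi, length.out = fs * 60)), 0) +
    rnorm(fs * 60, 0, 0.1)
  ch <- channel("pupil_diameter", fs, v)
  base <- structure(list(max_diameter = 8, bin_width = 0.1),
                    class = "pupil_baseline")
  p20 <- perclos(ch, base, 0, 60, analysis_config(perclos_fraction = 0.2))
  p40 <- perclos(ch, base, 0, 60, analysis_config(perclos_fraction = 0.4))
  expect_gte(p40$perclos_pct, p20$perclos_pct)

  ch2 <- channel("pupil_diameter", fs, v * 3)
  base2 <- structure(list(max_diameter = 24, bin_width = 0.1),
                     class = "pupil_baseline")
  expect_equal(perclos(ch2, base2, 0, 60)$perclos_pct, p20$perclos_pct)
})
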