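# Brute-force reference implementations, written directly from the measure
# definitions with plain loops.  They are deliberately independent of the
# package's vectorised code paths and are only run on short traces.

# Slow-eye-movement oracle: enumerate maximal |v| < speed_max runs of the
# smoothed first-difference velocity, split runs at sign reversals that
# persist >= reversal samples, keep segments with |endpoint displacement| >
# distance_min.
oracle_sem <- function(angle_values, fs, speed_max = 30, distance_min = 5,
                       smooth_ms = 50, reversal_ms = 100) {
  a <- angle_values
  n <- length(a)
  w <- max(1, round(smooth_ms / 1000 * fs))
  if (n < w + 1) return(NULL)
  v_raw <- diff(a) * fs
  nv <- length(v_raw)
  v <- numeric(nv)
  half <- (w - 1) %/% 2
  for (i in seq_len(nv)) {
    lo <- max(i - half, 1); hi <- min(i + (w - 1 - half), nv)
    v[i] <- mean(v_raw[lo:hi])
  }
  sub <- abs(v) < speed_max
  m <- max(1, round(reversal_ms / 1000 * fs))
  # carried sign
  s <- numeric(nv); last <- 0
  for (i in seq_len(nv)) {
    if (v[i] > 0) last <- 1 else if (v[i] < 0) last <- -1
    s[i] <- last
  }
  if (s[1] == 0) {
    first_nz <- s[s != 0][1]
    if (is.na(first_nz)) first_nz <- 1
    for (i in seq_len(nv)) { if (s[i] != 0) break; s[i] <- first_nz }
  }
  episodes <- list()
  i <- 1
  while (i <= nv) {
    if (!sub[i]) { i <- i + 1; next }
    j <- i
    while (j < nv && sub[j + 1]) j <- j + 1
    # split [i, j] at persistent sign changes
    seg_start <- i
    cur_sign <- s[i]
    k <- i
    while (k <= j) {
      if (s[k] != cur_sign) {
        run_end <- k
        while (run_end < j && s[run_end + 1] == s[k]) run_end <- run_end + 1
        if (run_end - k + 1 >= m) {
          episodes <- c(episodes, list(c(seg_start, k - 1)))
          seg_start <- k
          cur_sign <- s[k]
          k <- run_end + 1
          next
        } else {
          k <- run_end + 1
          next
        }
      }
      k <- k + 1
    }
    episodes <- c(episodes, list(c(seg_start, j)))
    i <- j + 1
  }
  out <- NULL
  for (e in episodes) {
    disp <- a[e[2] + 1] - a[e[1]]
    if (abs(disp) > distance_min) {
      out <- rbind(out, data.frame(
        start_s = (e[1] - 1) / fs, end_s = e[2] / fs,
        net_displacement_deg = disp))
    }
  }
  out
}

# PERCLOS oracle: sample-wise classification by the written rule, loops only.
oracle_perclos <- function(values, valid, fs, threshold, window_s,
                           bridge_ms = 100, min_ms = 400) {
  n <- length(values)
  state <- integer(n)  # 0 open, 1 closed, 2 excluded
  vals <- values
  i <- 1
  while (i <= n) {
    if (valid[i]) { i <- i + 1; next }
    j <- i
    while (j < n && !valid[j + 1]) j <- j + 1
    left_closed <- i > 1 && vals[i - 1] <= threshold
    right_closed <- j < n && vals[j + 1] <= threshold
    if (left_closed || right_closed) {
      state[i:j] <- 1L
    } else if ((j - i + 1) / fs * 1000 < bridge_ms && i > 1 && j < n) {
      for (k in i:j) {
        vals[k] <- vals[i - 1] + (vals[j + 1] - vals[i - 1]) *
          (k - i + 1) / (j - i + 2)
      }
    } else {
      state[i:j] <- 2L
    }
    i <- j + 1
  }
  for (i in seq_len(n)) {
    if (state[i] == 0L && vals[i] <= threshold) state[i] <- 1L
  }
  closed_s <- 0
  i <- 1
  while (i <= n) {
    if (state[i] != 1L) { i <- i + 1; next }
    j <- i
    while (j < n && state[j + 1] == 1L) j <- j + 1
    if ((j - i + 1) / fs * 1000 > min_ms) closed_s <- closed_s + (j - i + 1) / fs
    i <- j + 1
  }
  excluded_s <- sum(state == 2L) / fs
  if (excluded_s > 0.5 * window_s) return(NA_real_)
  100 * closed_s / (window_s - excluded_s)
}

# Repeated-measures ANOVA oracle via base R aov with an Error stratum.
oracle_rm_anova_f <- function(m) {
  d <- data.frame(y = as.vector(m),
                  subj = factor(rep(seq_len(nrow(m)), ncol(m))),
                  trial = factor(rep(seq_len(ncol(m)), each = nrow(m))))
  fit <- stats::aov(y ~ trial + Error(subj), data = d)
  s <- summary(fit)[["Error: Within"]][[1]]
  list(f = s["trial", "F value"], df_trial = s["trial", "Df"],
       df_error = s["Residuals", "Df"], p = s["trial", "Pr(>F)"])
}

# Short helper: constant-diameter pupil channel with injected dips.
make_pupil <- function(fs, dur_s, base = 8, dips = NULL, invalid = NULL) {
  n <- round(fs * dur_s)
  v <- rep(base, n)
  ok <- rep(TRUE, n)
  if (!is.null(dips)) {
    for (k in seq_len(nrow(dips))) {
      i1 <- round(dips$start[k] * fs) + 1
      i2 <- min(round(dips$end[k] * fs), n)
      v[i1:i2] <- dips$level[k]
    }
  }
  if (!is.null(invalid)) {
    for (k in seq_len(nrow(invalid))) {
      i1 <- round(invalid$start[k] * fs) + 1
      i2 <- min(round(invalid$end[k] * fs), n)
      ok[i1:i2] <- FALSE
    }
  }
  channel("pupil_diameter", fs, v, validity = ok)
}

# Fully populated synthetic key grid (no signals), for design-arithmetic
# checks.
full_design_rows <- function(n_participants, n_sessions = 8, trials = 3) {
  expand.grid(participant_id = sprintf("p%02d", seq_len(n_participants)),
              session = seq_len(n_sessions), trial = seq_len(trials),
              stringsAsFactors = FALSE)
}
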