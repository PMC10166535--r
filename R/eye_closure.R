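#' Baseline (maximum) pupil diameter from a reference window
#'
#' The baseline is the mode of the pupil-diameter histogram over a reference
#' recording taken in the participant's most alert state (the vigilance-task
#' block with the lowest KSS).  Ties between equally frequent bins are broken
#' toward the larger diameter.
#'
#' @param pupil A [channel()] of pupil diameter in millimetres with optional
#'   validity flags; at least 60 s of valid samples are required.
#' @param config An [analysis_config()]; `pupil_bin_mm` is the histogram bin
#'   width.
#' @return A list of class `"pupil_baseline"` with `max_diameter` (mm) and
#'   `bin_width`.
#' @export
baseline_pupil_max <- function(pupil, config = analysis_config()) {
  stopifnot(inherits(pupil, "channel"))
  v <- pupil$values
  if (!is.null(pupil$validity)) v <- v[pupil$validity]
  v <- v[is.finite(v)]
  if (length(v) / pupil$sampling_rate < 60) {
    stop("baseline reference needs >= 60 s of valid pupil samples")
  }
  bw <- config$pupil_bin_mm
  bin <- floor(v / bw)
  counts <- table(bin)
  best <- max(counts)
  centers <- (as.numeric(names(counts)) + 0.5) * bw
  md <- max(centers[counts == best])  # tie -> larger diameter
  structure(list(max_diameter = md, bin_width = bw), class = "pupil_baseline")
}

#' @export
print.pupil_baseline <- function(x, ...) {
  cat(sprintf("<pupil baseline: modal maximum %.2f mm (bin %.2f mm)>\n",
              x$max_diameter, x$bin_width))
  invisible(x)
}

# Classify each pupil sample as closed / open / excluded.
# closed: diameter <= fraction * baseline, or invalid and contiguous with such
#   a below-threshold sample (tracking loss caused by the closure itself);
# isolated invalid runs shorter than bridge_ms are linearly interpolated and
#   classified by threshold; longer isolated invalid runs are excluded.
.classify_closure <- function(values, valid, fs, threshold, bridge_ms) {
  n <- length(values)
  state <- integer(n)  # 0 open, 1 closed, 2 excluded
  vals <- values
  if (!all(valid)) {
    r <- rle(valid)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(!r$values)) {
      i1 <- starts[k]; i2 <- ends[k]
      left <- if (i1 > 1L) vals[i1 - 1L] <= threshold else FALSE
      right <- if (i2 < n) vals[i2 + 1L] <= threshold else FALSE
      if (left || right) {
        state[i1:i2] <- 1L                      # closure-adjacent loss
      } else if ((i2 - i1 + 1L) / fs * 1000 < bridge_ms && i1 > 1L && i2 < n) {
        vals[i1:i2] <- vals[i1 - 1L] +          # bridge short dropouts
          (vals[i2 + 1L] - vals[i1 - 1L]) * seq_len(i2 - i1 + 1L) / (i2 - i1 + 2L)
      } else {
        state[i1:i2] <- 2L                      # unexplained loss: exclude
      }
    }
  }
  und <- state == 0L
  state[und & vals <= threshold] <- 1L
  state
}

#' PERCLOS: percentage of time the eyes are closed
#'
#' A sample counts as closed when the pupil diameter is at or below
#' `perclos_fraction` (20%) of the baseline maximum; maximal closed runs
#' longer than `perclos_min_ms` (400 ms) are closure episodes.  PERCLOS is
#' the summed episode time as a percentage of the assessable window time
#' (window length minus time excluded for unexplained tracking loss).
#' Tracking-loss samples contiguous with below-threshold samples count as
#' closed; short isolated dropouts are bridged (see
#' \code{\link{analysis_config}}).
#'
#' @param pupil A [channel()] of pupil diameter (mm), sampling rate
#'   >= 30 Hz, with optional validity flags.
#' @param baseline A [baseline_pupil_max()] result.
#' @param start_time,end_time Trial window bounds, seconds.
#' @param config An [analysis_config()].
#' @return A list with `perclos_pct` (`NA` when more than half of the window
#'   is excluded tracking loss), and `episodes` (`data.frame` of `start_s`,
#'   `end_s`).
#' @export
perclos <- function(pupil, baseline, start_time, end_time,
                    config = analysis_config()) {
  stopifnot(inherits(pupil, "channel"), inherits(baseline, "pupil_baseline"),
            pupil$sampling_rate >= 30, end_time > start_time)
  ch <- channel_window(pupil, start_time, end_time)
  fs <- ch$sampling_rate
  valid <- if (is.null(ch$validity)) rep(TRUE, length(ch$values)) else ch$validity
  thr <- config$perclos_fraction * baseline$max_diameter
  state <- .classify_closure(ch$values, valid, fs, thr, config$perclos_bridge_ms)
  excluded_s <- sum(state == 2L) / fs
  denom <- (end_time - start_time) - excluded_s
  if (excluded_s > 0.5 * (end_time - start_time)) {
    warning("more than half of the trial is unexplained tracking loss; PERCLOS missing")
    return(list(perclos_pct = NA_real_,
                episodes = data.frame(start_s = numeric(0), end_s = numeric(0))))
  }
  r <- rle(state == 1L)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths / fs * 1000 > config$perclos_min_ms)
  tt <- channel_times(ch)
  eps <- data.frame(start_s = tt[starts[keep]],
                    end_s = tt[ends[keep]] + 1 / fs)
  closed_s <- sum(r$lengths[keep]) / fs
  list(perclos_pct = 100 * closed_s / denom, episodes = eps)
}
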