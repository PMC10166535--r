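#' Calibrate horizontal EOG to visual angle
#'
#' During a calibration block the participant fixates targets at known
#' lateral offsets on the display.  Each target offset maps to a visual angle
#' `theta = atan(offset / viewing_distance)` (degrees); the calibration
#' constant is the least-squares slope of the median EOG voltage per fixation
#' interval against the target angle.
#'
#' @param eog A [channel()] with the horizontal EOG voltage (microvolts)
#'   covering the calibration block.
#' @param schedule `data.frame` with columns `start_s`, `end_s`, `offset_cm`:
#'   the fixation intervals and target offsets.  At least two distinct
#'   offsets are required.
#' @param viewing_distance_cm Eye-to-display distance in centimetres.
#' @return A list of class `"eog_calibration"` with elements
#'   `volts_per_degree`, `targets` (the per-interval angle and median
#'   voltage), and `viewing_distance_cm`.
#' @export
#' @examples
#' t <- seq(0, 9 - 1e-3, by = 1e-3)
#' ang <- rep(atan(c(0, 30, -30) / 91.1) * 180 / pi, each = 3000)
#' cal <- calibrate_eog(channel("eog_h", 1000, 12 * ang),
#'   data.frame(start_s = c(0, 3, 6), end_s = c(3, 6, 9),
#'              offset_cm = c(0, 30, -30)), 91.1)
#' cal$volts_per_degree
calibrate_eog <- function(eog, schedule, viewing_distance_cm) {
  stopifnot(inherits(eog, "channel"),
            all(c("start_s", "end_s", "offset_cm") %in% names(schedule)),
            viewing_distance_cm > 0)
  if (length(unique(schedule$offset_cm)) < 2L) {
    stop("calibration schedule needs >= 2 distinct target offsets")
  }
  tt <- channel_times(eog)
  theta <- atan(schedule$offset_cm / viewing_distance_cm) * 180 / pi
  med <- vapply(seq_len(nrow(schedule)), function(i) {
    v <- eog$values[tt >= schedule$start_s[i] & tt < schedule$end_s[i]]
    if (!length(v)) stop("EOG does not cover calibration interval ", i)
    stats::median(v)
  }, numeric(1))
  slope <- stats::coef(stats::lm(med ~ theta))[["theta"]]
  if (!is.finite(slope) || abs(slope) < 1) {
    stop(sprintf("implausible EOG calibration: slope %.3f uV/deg", slope))
  }
  structure(list(volts_per_degree = slope,
                 targets = data.frame(theta_deg = theta, median_uv = med),
                 viewing_distance_cm = viewing_distance_cm),
            class = "eog_calibration")
}

#' @export
print.eog_calibration <- function(x, ...) {
  cat(sprintf("<EOG calibration: %.2f uV/deg from %d fixation targets>\n",
              x$volts_per_degree, nrow(x$targets)))
  invisible(x)
}

#' Convert an EOG voltage channel to gaze angle
#'
#' Applies a zero-phase 4th-order Butterworth low-pass (default corner 15 Hz)
#' and divides by the calibration constant.  Zero-phase (forward-backward)
#' filtering keeps episode timestamps unlagged.
#'
#' @param eog A [channel()] of horizontal EOG voltage, sampling rate
#'   >= 100 Hz.
#' @param calibration An [calibrate_eog()] result.
#' @param config An [analysis_config()]; `eog_lowpass_hz` is used.
#' @return A [channel()] named `"gaze_angle"` in degrees, same rate and
#'   start time.
#' @export
eog_to_angle <- function(eog, calibration, config = analysis_config()) {
  stopifnot(inherits(eog, "channel"), inherits(calibration, "eog_calibration"),
            eog$sampling_rate >= 100)
  bf <- signal::butter(4, config$eog_lowpass_hz / (eog$sampling_rate / 2),
                       type = "low")
  v <- .zero_phase(bf, eog$values)
  channel("gaze_angle", eog$sampling_rate,
          v / calibration$volts_per_degree, start_time = eog$start_time)
}

# Moving average with partial windows at the edges; window length w (samples).
.moving_average <- function(x, w) {
  if (w <= 1L) return(x)
  cs <- cumsum(c(0, x))
  n <- length(x)
  half <- (w - 1L) %/% 2L
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + (w - 1L - half), n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Sign vector where zeros inherit the preceding non-zero sign (leading zeros
# inherit the first non-zero sign; an all-zero vector is a single segment).
.carry_sign <- function(v) {
  s <- sign(v)
  nz <- s != 0
  if (!any(nz)) return(rep(1, length(v)))
  idx <- cummax(ifelse(nz, seq_along(s), 0L))
  first <- s[which(nz)[1]]
  ifelse(idx == 0L, first, s[pmax(idx, 1L)])
}

#' Detect slow eye movements in a gaze-angle series
#'
#' A slow eye movement (SEM) is a slow horizontal ocular drift: a stretch of
#' the gaze-angle trace whose speed stays below `sem_speed_max` (30 deg/s)
#' and whose net angular displacement exceeds `sem_distance_min` (5 deg).
#' The velocity is the first difference smoothed by a short moving average
#' (`sem_smooth_ms`); maximal sub-threshold runs are split where the velocity
#' sign reverses and the reversal persists longer than `sem_reversal_ms`,
#' so that back-and-forth drifts are scored as separate episodes.
#'
#' @param angle A [channel()] of gaze angle in degrees (see
#'   [eog_to_angle()]).
#' @param config An [analysis_config()].
#' @return A `data.frame` with one row per episode: `start_s`, `end_s`,
#'   `net_displacement_deg`, `mean_speed_deg_s`.  Zero rows when the series
#'   is shorter than the smoothing window (with a warning) or when no run
#'   qualifies.
#' @export
detect_sem <- function(angle, config = analysis_config()) {
  stopifnot(inherits(angle, "channel"))
  fs <- angle$sampling_rate
  a <- angle$values
  w <- max(1L, round(config$sem_smooth_ms / 1000 * fs))
  if (length(a) < w + 1L) {
    warning("gaze series shorter than the velocity smoothing window; no SEM detected")
    return(.empty_sem())
  }
  v <- diff(a) * fs
  v <- .moving_average(v, w)
  sub <- abs(v) < config$sem_speed_max
  runs <- rle(sub)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  m <- max(1L, round(config$sem_reversal_ms / 1000 * fs))
  out <- list()
  tt <- channel_times(angle)
  for (k in which(runs$values)) {
    i1 <- starts[k]; i2 <- ends[k]
    segs <- .split_run(v[i1:i2], m)
    for (sg in segs) {
      j1 <- i1 + sg[1] - 1L; j2 <- i1 + sg[2] - 1L
      # velocity index j spans samples j..j+1 of the angle trace
      disp <- if (config$sem_distance_mode == "path") {
        sum(abs(diff(a[j1:(j2 + 1L)])))
      } else {
        a[j2 + 1L] - a[j1]
      }
      if (abs(disp) > config$sem_distance_min) {
        out[[length(out) + 1L]] <- data.frame(
          start_s = tt[j1], end_s = tt[j2 + 1L],
          net_displacement_deg = a[j2 + 1L] - a[j1],
          mean_speed_deg_s = mean(abs(v[j1:j2])))
      }
    }
  }
  if (!length(out)) return(.empty_sem())
  do.call(rbind, out)
}

.empty_sem <- function() {
  data.frame(start_s = numeric(0), end_s = numeric(0),
             net_displacement_deg = numeric(0), mean_speed_deg_s = numeric(0))
}

# Split a velocity run into sign-consistent segments: a sign change opens a
# new segment only when the new sign persists >= m samples; shorter flips are
# absorbed.  Returns a list of c(first, last) indices relative to the run.
.split_run <- function(v, m) {
  s <- .carry_sign(v)
  r <- rle(s)
  re <- cumsum(r$lengths)
  rs <- re - r$lengths + 1L
  segs <- list()
  cur_start <- 1L
  cur_sign <- r$values[1]
  if (length(r$lengths) > 1L) {
    for (q in 2:length(r$lengths)) {
      if (r$values[q] != cur_sign && r$lengths[q] >= m) {
        segs[[length(segs) + 1L]] <- c(cur_start, rs[q] - 1L)
        cur_start <- rs[q]
        cur_sign <- r$values[q]
      }
    }
  }
  segs[[length(segs) + 1L]] <- c(cur_start, length(v))
  segs
}

#' Percentage of trial time occupied by slow eye movements
#'
#' Episodes are clipped to the closed-open trial window and their durations
#' summed; the result is expressed as a percentage of the window length.
#'
#' @param episodes Episode table from [detect_sem()].
#' @param start_time,end_time Trial window bounds in seconds.
#' @return Percentage in `[0, 100]`.  Overlapping episodes violate the
#'   detector contract and raise an error.
#' @export
#' @examples
#' percent_sem(data.frame(start_s = c(10, 50), end_s = c(25, 65),
#'                        net_displacement_deg = c(8, -7),
#'                        mean_speed_deg_s = c(10, 12)), 0, 300)
percent_sem <- function(episodes, start_time, end_time) {
  stopifnot(end_time > start_time)
  if (nrow(episodes) == 0L) return(0)
  ep <- episodes[order(episodes$start_s), , drop = FALSE]
  if (any(ep$end_s[-nrow(ep)] > ep$start_s[-1] + 1e-12)) {
    stop("overlapping SEM episodes: detector contract violated")
  }
  s <- pmax(ep$start_s, start_time)
  e <- pmin(ep$end_s, end_time)
  100 * sum(pmax(e - s, 0)) / (end_time - start_time)
}
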