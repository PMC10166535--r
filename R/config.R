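#' Analysis configuration
#'
#' Collects every tunable constant of the measure-extraction operators in one
#' list, with the study's published values as defaults.  All extraction
#' functions take an `config` argument so a cohort run is reproducible from a
#' single object.
#'
#' @param sem_speed_max Maximum eye-movement speed of a slow eye movement
#'   (SEM), degrees/s.  Movements at or above this speed are not SEM.
#' @param sem_distance_min Minimum net angular displacement of an SEM episode,
#'   degrees (strict: displacement must exceed this).
#' @param sem_smooth_ms Moving-average window applied to the EOG-derived
#'   velocity before thresholding, milliseconds.
#' @param sem_reversal_ms Minimum persistence of a velocity sign reversal for
#'   it to split a sub-threshold run into separate drift episodes,
#'   milliseconds.
#' @param eog_lowpass_hz Low-pass corner applied to the horizontal EOG before
#'   conversion to visual angle, Hz.
#' @param eeg_highpass_tc High-pass time constant for EEG preprocessing,
#'   seconds (corner frequency 1 / (2 * pi * tc)).
#' @param eeg_lowpass_hz EEG low-pass corner, Hz.
#' @param eeg_segment_s Length of the artifact-screened EEG analysis segments,
#'   seconds.
#' @param eeg_artifact_uv Absolute-amplitude artifact threshold per segment,
#'   microvolts; a segment containing any sample above it is discarded.
#' @param welch_window_s Welch sub-window length, seconds.
#' @param welch_overlap Fractional overlap of Welch sub-windows.
#' @param theta_band,alpha_band Band edges in Hz, `c(low, high)`.
#' @param perclos_fraction Closure threshold as a fraction of the baseline
#'   maximum pupil diameter.
#' @param perclos_min_ms Minimum duration of a closure episode, milliseconds
#'   (strict: episodes must be longer).
#' @param perclos_bridge_ms Isolated tracking-loss runs shorter than this are
#'   bridged by linear interpolation; longer isolated runs are dropped from
#'   the PERCLOS denominator.
#' @param pupil_bin_mm Histogram bin width for the modal baseline pupil
#'   diameter, millimetres.
#' @param ord_tolerance Inter-rater concordance tolerance in ORD levels
#'   (0 = exact agreement).
#' @param ord_gate Minimum pairwise concordance rate for rater qualification.
#' @param kss_high,kss_low KSS cut points of the participant-selection rule
#'   (responses `>= kss_high` and `<= kss_low` are counted separately).
#' @param kss_min_count Minimum count on each side of the KSS cut for a
#'   participant to be retained.
#' @param sem_distance_mode Either `"net"` (endpoint-to-endpoint displacement,
#'   the default) or `"path"` (summed absolute displacement) as the SEM
#'   distance criterion.
#'
#' @return A list of class `"drowsival_config"`.
#' @export
#' @examples
#' cfg <- analysis_config()
#' cfg$sem_speed_max
analysis_config <- function(sem_speed_max = 30,
                            sem_distance_min = 5,
                            sem_smooth_ms = 50,
                            sem_reversal_ms = 100,
                            eog_lowpass_hz = 15,
                            eeg_highpass_tc = 0.3,
                            eeg_lowpass_hz = 30,
                            eeg_segment_s = 15,
                            eeg_artifact_uv = 100,
                            welch_window_s = 2,
                            welch_overlap = 0.5,
                            theta_band = c(4, 7.9),
                            alpha_band = c(8, 12),
                            perclos_fraction = 0.20,
                            perclos_min_ms = 400,
                            perclos_bridge_ms = 100,
                            pupil_bin_mm = 0.1,
                            ord_tolerance = 1,
                            ord_gate = 0.7,
                            kss_high = 8,
                            kss_low = 7,
                            kss_min_count = 3,
                            sem_distance_mode = c("net", "path")) {
  sem_distance_mode <- match.arg(sem_distance_mode)
  cfg <- list(
    sem_speed_max = sem_speed_max, sem_distance_min = sem_distance_min,
    sem_smooth_ms = sem_smooth_ms, sem_reversal_ms = sem_reversal_ms,
    eog_lowpass_hz = eog_lowpass_hz,
    eeg_highpass_tc = eeg_highpass_tc, eeg_lowpass_hz = eeg_lowpass_hz,
    eeg_segment_s = eeg_segment_s, eeg_artifact_uv = eeg_artifact_uv,
    welch_window_s = welch_window_s, welch_overlap = welch_overlap,
    theta_band = theta_band, alpha_band = alpha_band,
    perclos_fraction = perclos_fraction, perclos_min_ms = perclos_min_ms,
    perclos_bridge_ms = perclos_bridge_ms, pupil_bin_mm = pupil_bin_mm,
    ord_tolerance = ord_tolerance, ord_gate = ord_gate,
    kss_high = kss_high, kss_low = kss_low, kss_min_count = kss_min_count,
    sem_distance_mode = sem_distance_mode)
  stopifnot(sem_speed_max > 0, sem_distance_min > 0,
            perclos_fraction > 0, perclos_fraction < 1,
            theta_band[1] < theta_band[2], alpha_band[1] < alpha_band[2])
  class(cfg) <- "drowsival_config"
  cfg
}

#' @export
print.drowsival_config <- function(x, ...) {
  cat("Drowsiness-measure extraction configuration\n")
  cat(sprintf("  SEM: speed < %g deg/s, displacement > %g deg (%s)\n",
              x$sem_speed_max, x$sem_distance_min, x$sem_distance_mode))
  cat(sprintf("  EEG: segments %g s, artifact |x| <= %g uV, theta %g-%g Hz, alpha %g-%g Hz\n",
              x$eeg_segment_s, x$eeg_artifact_uv,
              x$theta_band[1], x$theta_band[2],
              x$alpha_band[1], x$alpha_band[2]))
  cat(sprintf("  PERCLOS: diameter <= %g%% of baseline for > %g ms\n",
              100 * x$perclos_fraction, x$perclos_min_ms))
  cat(sprintf("  ORD gate: pairwise concordance >= %g (tolerance %d level)\n",
              x$ord_gate, x$ord_tolerance))
  invisible(x)
}
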