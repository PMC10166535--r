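#' Preprocess an EEG channel
#'
#' Applies the recording chain used for spectral analysis: a first-order
#' high-pass with time constant `eeg_highpass_tc` (0.3 s, i.e. corner
#' frequency 1 / (2 * pi * 0.3) ~ 0.53 Hz) followed by a 4th-order
#' Butterworth low-pass at `eeg_lowpass_hz` (30 Hz).  Both are applied
#' forward-backward (zero phase).  The mains notch is assumed to have been
#' applied at recording time and is not re-applied.
#'
#' @param eeg A [channel()] of EEG voltage in microvolts.
#' @param config An [analysis_config()].
#' @return A [channel()] with the filtered signal.
#' @export
preprocess_eeg <- function(eeg, config = analysis_config()) {
  stopifnot(inherits(eeg, "channel"))
  fs <- eeg$sampling_rate
  fc_hp <- 1 / (2 * pi * config$eeg_highpass_tc)
  hp <- signal::butter(1, fc_hp / (fs / 2), type = "high")
  lp <- signal::butter(4, config$eeg_lowpass_hz / (fs / 2), type = "low")
  v <- .zero_phase(lp, .zero_phase(hp, eeg$values))
  channel(eeg$name, fs, v, start_time = eeg$start_time)
}

#' Segment a trial's EEG and screen artifacts
#'
#' Tiles the trial window with consecutive non-overlapping segments of
#' `eeg_segment_s` seconds (20 per 300-s trial) and keeps those whose
#' absolute amplitude never exceeds `eeg_artifact_uv`.
#'
#' @param eeg A (preprocessed) EEG [channel()] covering the trial.
#' @param start_time,end_time Trial window bounds, seconds.
#' @param config An [analysis_config()].
#' @return A list of numeric vectors, one per artifact-free segment (possibly
#'   empty, with a warning — the trial's band power is then missing, not
#'   zero).
#' @export
segment_trial_eeg <- function(eeg, start_time, end_time,
                              config = analysis_config()) {
  stopifnot(inherits(eeg, "channel"), end_time > start_time)
  fs <- eeg$sampling_rate
  seg_n <- round(config$eeg_segment_s * fs)
  tt <- channel_times(eeg)
  idx <- which(tt >= start_time & tt < end_time)
  if (!length(idx)) stop("EEG channel does not cover the trial window")
  x <- eeg$values[idx]
  n_seg <- length(x) %/% seg_n
  segs <- vector("list", 0)
  for (k in seq_len(n_seg)) {
    s <- x[((k - 1L) * seg_n + 1L):(k * seg_n)]
    if (max(abs(s)) <= config$eeg_artifact_uv) segs[[length(segs) + 1L]] <- s
  }
  if (!length(segs)) {
    warning("no artifact-free EEG segments in trial; band power will be missing")
  }
  segs
}

#' Welch power spectral density
#'
#' Averaged modified periodogram with a Hann taper: the segment is cut into
#' sub-windows of `window_s` seconds with fractional `overlap`, each tapered
#' and Fourier-transformed, and the one-sided PSDs averaged.
#'
#' @param x Numeric sample vector.
#' @param fs Sampling rate, Hz.
#' @param window_s Sub-window length, seconds.
#' @param overlap Fractional overlap in `[0, 1)`.
#' @return A list with `freq` (Hz, 0 to Nyquist) and `psd` (power density,
#'   input-units squared per Hz); `sum(psd) * df` approximates the signal
#'   variance (Parseval).
#' @export
welch_psd <- function(x, fs, window_s = 2, overlap = 0.5) {
  nwin <- round(window_s * fs)
  stopifnot(nwin >= 8, length(x) >= nwin, overlap >= 0, overlap < 1)
  step <- max(1L, round(nwin * (1 - overlap)))
  starts <- seq(1L, length(x) - nwin + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, nwin - 1) / nwin)  # periodic Hann
  u <- sum(w^2)
  nf <- nwin %/% 2L + 1L
  acc <- numeric(nf)
  for (s0 in starts) {
    seg <- x[s0:(s0 + nwin - 1L)]
    X <- stats::fft(seg * w)[seq_len(nf)]
    p <- (Mod(X)^2) / (fs * u)
    # one-sided: double everything except DC (and Nyquist when nwin is even)
    dbl <- rep(2, nf); dbl[1] <- 1
    if (nwin %% 2L == 0L) dbl[nf] <- 1
    acc <- acc + p * dbl
  }
  list(freq = seq(0, nf - 1) * fs / nwin, psd = acc / length(starts))
}

#' Integrate a PSD over a frequency band
#'
#' Treats the PSD as piecewise constant over bins of width `df` centred on
#' the FFT frequencies and integrates it over exactly `[low, high]`, with
#' fractional contributions from the edge bins.  Band-integrated power of a
#' flat PSD is therefore proportional to the exact bandwidth, and adjacent
#' bands add up without double counting.
#'
#' @param psd A [welch_psd()] result.
#' @param band `c(low, high)` in Hz.
#' @return Band power (input-units squared).
#' @export
bandpower <- function(psd, band) {
  stopifnot(band[1] < band[2])
  df <- psd$freq[2] - psd$freq[1]
  lo_edge <- pmax(psd$freq - df / 2, 0)
  hi_edge <- psd$freq + df / 2
  width <- pmax(pmin(hi_edge, band[2]) - pmax(lo_edge, band[1]), 0)
  sum(psd$psd * width)
}

#' Mean band power of a trial's EEG segments
#'
#' Welch PSD per artifact-free segment, integrated over the band, then
#' averaged (unweighted) across segments.
#'
#' @param segments List of sample vectors from [segment_trial_eeg()].
#' @param band `c(low, high)` in Hz.
#' @param fs Sampling rate, Hz.
#' @param config An [analysis_config()]; Welch window and overlap are used.
#' @return Mean band power in microvolts squared, or `NA` when no valid
#'   segment exists.
#' @export
#' @examples
#' x <- 50 * sin(2 * pi * 10 * seq(0, 15 - 1e-3, by = 1e-3))
#' trial_bandpower(list(x), c(8, 12), 1000)  # ~ 50^2 / 2 = 1250
trial_bandpower <- function(segments, band, fs, config = analysis_config()) {
  if (!length(segments)) return(NA_real_)
  mean(vapply(segments, function(s) {
    bandpower(welch_psd(s, fs, config$welch_window_s, config$welch_overlap),
              band)
  }, numeric(1)))
}
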