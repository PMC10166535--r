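#' Signal channel
#'
#' A uniformly sampled signal from one device during one session.  Time is
#' seconds from session start; channels from different devices may start at
#' different times.
#'
#' @param name Channel label, one of `"eog_h"`, `"eeg_c3"`,
#'   `"pupil_diameter"`, `"lane_position"` (other labels are allowed but not
#'   used by the extraction pipeline).
#' @param sampling_rate Sampling rate in Hz, positive.
#' @param values Numeric sample vector (microvolts for EOG/EEG, millimetres
#'   for pupil diameter, centimetres for lane position).
#' @param start_time Time of the first sample, seconds from session start.
#' @param validity Optional logical vector, one flag per sample, `FALSE` where
#'   the device lost tracking.
#' @return An object of class `"channel"`.
#' @export
channel <- function(name, sampling_rate, values, start_time = 0,
                    validity = NULL) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(sampling_rate), length(sampling_rate) == 1L,
            sampling_rate > 0, length(values) > 0)
  values <- as.numeric(values)
  if (!is.null(validity)) {
    stopifnot(is.logical(validity), length(validity) == length(values))
  }
  structure(list(name = name, sampling_rate = sampling_rate,
                 start_time = start_time, values = values,
                 validity = validity),
            class = "channel")
}

#' @export
print.channel <- function(x, ...) {
  cat(sprintf("<channel %s: %d samples at %g Hz, t0 = %g s%s>\n",
              x$name, length(x$values), x$sampling_rate, x$start_time,
              if (is.null(x$validity)) ""
              else sprintf(", %d invalid", sum(!x$validity))))
  invisible(x)
}

#' Sample times of a channel
#' @param x A [channel()].
#' @return Numeric vector of sample times in seconds.
#' @export
channel_times <- function(x) {
  x$start_time + (seq_along(x$values) - 1L) / x$sampling_rate
}

#' Slice a channel to a closed-open time window
#'
#' Keeps the samples whose time falls in `[start, end)`.
#'
#' @param x A [channel()].
#' @param start,end Window bounds in seconds from session start.
#' @return A [channel()] covering the window (possibly with zero-length values
#'   if no sample falls inside, in which case an error is raised).
#' @export
channel_window <- function(x, start, end) {
  t <- channel_times(x)
  keep <- t >= start & t < end
  if (!any(keep)) stop("no samples of channel '", x$name,
                       "' fall inside [", start, ", ", end, ")")
  channel(x$name, x$sampling_rate, x$values[keep], start_time = t[which(keep)[1]],
          validity = if (is.null(x$validity)) NULL else x$validity[keep])
}

#' Session recording
#'
#' One participant-session bundle: the signal channels plus the timed
#' Karolinska sleepiness scale (KSS) prompts and verbal responses that anchor
#' trial segmentation.
#'
#' @param participant_id Participant label.
#' @param session_index Session number, 1-8 in the study design.
#' @param channels Named list of [channel()] objects.
#' @param kss_prompts `data.frame` with columns `time` (seconds, strictly
#'   increasing) and `response` (integer 1-9).
#' @return An object of class `"recording"`.
#' @export
recording <- function(participant_id, session_index, channels, kss_prompts) {
  stopifnot(is.list(channels),
            all(vapply(channels, inherits, logical(1), "channel")),
            is.data.frame(kss_prompts),
            all(c("time", "response") %in% names(kss_prompts)))
  if (nrow(kss_prompts)) {
    stopifnot(all(diff(kss_prompts$time) > 0),
              all(kss_prompts$response >= 1 & kss_prompts$response <= 9))
  }
  stopifnot(session_index >= 1, session_index <= 8)
  names(channels) <- vapply(channels, `[[`, character(1), "name")
  structure(list(participant_id = participant_id,
                 session_index = as.integer(session_index),
                 channels = channels, kss_prompts = kss_prompts),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording %s session %d: %d channels, %d KSS prompts>\n",
              x$participant_id, x$session_index, length(x$channels),
              nrow(x$kss_prompts)))
  invisible(x)
}

#' Cut a recording into trial windows anchored on KSS prompts
#'
#' Each trial is the 5 minutes of driving that end at a KSS prompt: the window
#' is `[prompt - trial_s, prompt)` in session time and carries the KSS
#' response given at the prompt.  Prompts earlier than `trial_s` seconds after
#' the start of every channel cannot support a full trial and are dropped
#' with a warning.
#'
#' @param rec A [recording()].
#' @param trial_s Trial duration in seconds (default 300).
#' @return A `data.frame` with one row per usable prompt and columns
#'   `participant_id`, `session`, `trial` (index within session),
#'   `trial_order` (global 1-24 index, `3 * (session - 1) + trial`),
#'   `start_time`, `end_time`, `kss`.
#' @export
#' @examples
#' rec <- recording("p1", 1,
#'   list(channel("lane_position", 10, rnorm(10500))),
#'   data.frame(time = c(300, 660, 1020), response = c(2, 3, 5)))
#' slice_trials(rec)
slice_trials <- function(rec, trial_s = 300) {
  stopifnot(inherits(rec, "recording"))
  if (nrow(rec$kss_prompts) == 0L) stop("recording has no KSS prompts")
  t0 <- max(vapply(rec$channels, `[[`, numeric(1), "start_time"))
  usable <- rec$kss_prompts$time >= t0 + trial_s - 1e-9
  if (any(!usable)) {
    warning(sprintf("dropping %d KSS prompt(s) earlier than %g s into the recording",
                    sum(!usable), trial_s))
  }
  p <- rec$kss_prompts[usable, , drop = FALSE]
  if (nrow(p) == 0L) stop("no usable KSS prompts: all fall within ",
                          trial_s, " s of recording start")
  trial <- seq_len(nrow(p))
  data.frame(participant_id = rec$participant_id,
             session = rec$session_index,
             trial = trial,
             trial_order = 3L * (rec$session_index - 1L) + trial,
             start_time = p$time - trial_s,
             end_time = p$time,
             kss = as.integer(p$response),
             stringsAsFactors = FALSE)
}
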