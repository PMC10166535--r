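#' Standard deviation of lateral position (SDLP)
#'
#' The classic weaving measure of driving impairment: the sample standard
#' deviation (n - 1 denominator) of the car's lateral lane position over the
#' trial window.  Translation invariant and scale equivariant; no
#' lane-departure clipping is applied.
#'
#' @param lane A [channel()] of lateral position in centimetres (signed,
#'   relative to lane centre).
#' @param start_time,end_time Trial window bounds, seconds.
#' @param min_coverage_s Minimum span of samples required inside the window
#'   (default 30 s); otherwise the value is missing with a warning.
#' @return SDLP in centimetres, or `NA` for insufficient coverage.
#' @export
#' @examples
#' ch <- channel("lane_position", 10, rnorm(3000, sd = 25))
#' sdlp(ch, 0, 300)
sdlp <- function(lane, start_time, end_time, min_coverage_s = 30) {
  stopifnot(inherits(lane, "channel"), end_time > start_time)
  tt <- channel_times(lane)
  x <- lane$values[tt >= start_time & tt < end_time]
  if (length(x) / lane$sampling_rate < min_coverage_s) {
    warning("fewer than ", min_coverage_s,
            " s of lane-position samples inside the trial; SDLP missing")
    return(NA_real_)
  }
  stats::sd(x)
}
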