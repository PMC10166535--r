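#' Map observer-rating labels to points
#'
#' The observer rating of drowsiness (ORD) scale runs D1 (not drowsy) to D5
#' (extremely drowsy), scored 1-5 points; the "S" (sleeping) label also
#' scores 5 points.
#'
#' @param labels Character vector of codes (`"D1"` ... `"D5"`, `"S"`).
#' @return Integer vector of points.  Unknown codes raise an error naming
#'   the offending segment.
#' @export
#' @examples
#' labels_to_points(c("D1", "D3", "S"))
labels_to_points <- function(labels) {
  map <- c(D1 = 1L, D2 = 2L, D3 = 3L, D4 = 4L, D5 = 5L, S = 5L)
  pts <- map[as.character(labels)]
  if (anyNA(pts)) {
    bad <- which(is.na(pts))[1]
    stop("unknown ORD label '", labels[bad], "' at segment ", bad)
  }
  unname(pts)
}

#' Trial-level ORD score
#'
#' The grand mean of the per-segment, per-rater points over the whole trial:
#' equivalently, the segmentwise rater means averaged over segments.
#'
#' @param ratings Numeric matrix of points with one row per 5-s segment and
#'   one column per rater, or a list of equal-length per-rater point
#'   vectors.
#' @return Mean score, a real number in `[1, 5]`.
#' @export
#' @examples
#' trial_ord_score(cbind(a = c(1, 3), b = c(2, 2), c = c(3, 1)))  # 2
trial_ord_score <- function(ratings) {
  if (is.list(ratings) && !is.data.frame(ratings)) {
    len <- vapply(ratings, length, integer(1))
    if (length(unique(len)) != 1L) {
      stop("raters cover unequal numbers of segments")
    }
    ratings <- do.call(cbind, ratings)
  }
  ratings <- as.matrix(ratings)
  stopifnot(nrow(ratings) >= 1L, ncol(ratings) >= 1L)
  if (anyNA(ratings)) stop("missing rater labels are not allowed")
  if (any(ratings < 1 | ratings > 5)) stop("ORD points must lie in 1..5")
  mean(ratings)
}

#' Pairwise inter-rater concordance rate
#'
#' The fraction of segments on which two raters agree to within `tolerance`
#' ORD levels (1 by default; 0 demands exact agreement).
#'
#' @param a,b Equal-length numeric vectors of per-segment points.
#' @param tolerance Allowed absolute level difference.
#' @return Fraction in `[0, 1]`.
#' @export
concordance_rate <- function(a, b, tolerance = 1) {
  if (length(a) != length(b)) stop("rating sequences differ in length")
  if (!length(a)) stop("empty rating sequences")
  mean(abs(a - b) <= tolerance)
}

#' Rater-qualification gate
#'
#' Computes the concordance rate for every rater pair and checks the
#' qualification rule: every pair must reach at least `ord_gate` (0.7).
#'
#' @param ratings Matrix of points, segments x raters (>= 2 raters).
#' @param config An [analysis_config()]; `ord_tolerance` and `ord_gate` are
#'   used.
#' @return A list with `pairs` (`data.frame`: `rater_a`, `rater_b`, `rate`)
#'   and `pass` (logical).
#' @export
ord_gate <- function(ratings, config = analysis_config()) {
  ratings <- as.matrix(ratings)
  stopifnot(ncol(ratings) >= 2L)
  if (is.null(colnames(ratings))) {
    colnames(ratings) <- paste0("rater", seq_len(ncol(ratings)))
  }
  cmb <- utils::combn(ncol(ratings), 2)
  pairs <- data.frame(
    rater_a = colnames(ratings)[cmb[1, ]],
    rater_b = colnames(ratings)[cmb[2, ]],
    rate = apply(cmb, 2, function(ij) {
      concordance_rate(ratings[, ij[1]], ratings[, ij[2]],
                       config$ord_tolerance)
    }))
  list(pairs = pairs, pass = all(pairs$rate >= config$ord_gate))
}
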