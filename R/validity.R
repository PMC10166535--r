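#' Convergent-validity analysis of trial-level drowsiness measures
#'
#' The central fit: given a trial-level table of the seven drowsiness
#' measures, runs the full validation battery.  For every unordered measure
#' pair, Pearson's r is computed across trials within each participant,
#' Fisher z-transformed, and the per-participant z values are tested against
#' zero with a one-sample t-test (with 95% confidence interval).  For every
#' measure, a one-way repeated-measures ANOVA with the 24-level trial factor
#' tests whether the measure changed over the session sequence, and the
#' per-trial group time course (mean and standard error) is summarised.
#'
#' @param tab A measure table (from [assemble_measure_table()],
#'   [read_trial_table()] or [extract_measures()]).
#' @param measures Measure columns to analyse (default: all seven).
#' @param kss_filter Apply the participant-selection rule on KSS range (see
#'   [filter_participants_by_kss_range()]) before analysis?  Default `TRUE`,
#'   mirroring the study design; disable when the table already contains only
#'   selected participants.
#' @param config An [analysis_config()].
#' @param conf_level Confidence level of the pairwise intervals.
#' @return An object of class `"ord_validity"`: a list with
#'   \describe{
#'     \item{pairs}{`data.frame`, one row per measure pair: `measure_a`,
#'       `measure_b`, `mean_z`, `ci_low`, `ci_high`, `t`, `df`, `p`, `n`.}
#'     \item{correlations}{the per-participant r and z values.}
#'     \item{anova}{named list of [rm_anova()] results, one per measure.}
#'     \item{time_course}{named list of [time_course_summary()] tables.}
#'     \item{table}{the analysed (possibly filtered) measure table.}
#'     \item{n_participants}{number of participants analysed.}
#'   }
#' @export
#' @examples
#' tab <- simulate_measure_table(sim_config(n_participants = 6), seed = 1)
#' fit <- ord_validity(tab, kss_filter = FALSE)
#' print(fit)
#' coef(fit)["ord_mean", "kss"]
ord_validity <- function(tab, measures = MEASURE_COLS, kss_filter = TRUE,
                         config = analysis_config(), conf_level = 0.95) {
  stopifnot(is.data.frame(tab), all(measures %in% names(tab)))
  if (!"trial_order" %in% names(tab)) {
    tab$trial_order <- 3L * (as.integer(tab$session) - 1L) +
      as.integer(tab$trial)
  }
  if (kss_filter) tab <- filter_participants_by_kss_range(tab, config)
  n_part <- length(unique(tab$participant_id))
  if (n_part < 2) stop("fewer than 2 participants after filtering")

  cors <- participant_correlations(tab, measures)
  cors$z <- fisher_z(cors$r)
  key <- paste(cors$measure_a, cors$measure_b, sep = ":")
  pairs <- do.call(rbind, lapply(split(cors, key)[unique(key)], function(d) {
    g <- group_z_test(d$z, conf_level)
    data.frame(measure_a = d$measure_a[1], measure_b = d$measure_b[1],
               mean_z = g$mean_z, ci_low = g$ci_low, ci_high = g$ci_high,
               t = g$t, df = g$df, p = g$p, n = g$n,
               stringsAsFactors = FALSE)
  }))
  rownames(pairs) <- NULL

  anovas <- lapply(measures, function(m) suppressMessages(rm_anova(tab, m)))
  names(anovas) <- measures
  tc <- lapply(measures, function(m) time_course_summary(tab, m))
  names(tc) <- measures

  structure(list(pairs = pairs, correlations = cors, anova = anovas,
                 time_course = tc, table = tab, n_participants = n_part,
                 measures = measures, conf_level = conf_level),
            class = "ord_validity")
}

.stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' @export
print.ord_validity <- function(x, digits = 2, ...) {
  cat(sprintf("Convergent-validity analysis: %d participants, %d trials, %d measures\n\n",
              x$n_participants, nrow(x$table), length(x$measures)))
  cat("Mean Fisher z by measure pair (95% CI):\n")
  p <- x$pairs
  lab <- sprintf("%.*f%s (%.*f-%.*f)", digits, p$mean_z, .stars(p$p),
                 digits, p$ci_low, digits, p$ci_high)
  out <- data.frame(pair = paste(p$measure_a, p$measure_b, sep = " ~ "),
                    `mean z (CI)` = lab, check.names = FALSE)
  print(out, row.names = FALSE, right = FALSE)
  cat("\nSignif.: *** p<0.001, ** p<0.01, * p<0.05\n")
  invisible(x)
}

#' Mean Fisher-z matrix of a validity fit
#'
#' @param object An [ord_validity()] fit.
#' @param ... Unused.
#' @return Symmetric matrix of mean Fisher-z values across participants,
#'   with `NA` on the diagonal.
#' @export
coef.ord_validity <- function(object, ...) {
  m <- object$measures
  z <- matrix(NA_real_, length(m), length(m), dimnames = list(m, m))
  for (i in seq_len(nrow(object$pairs))) {
    a <- object$pairs$measure_a[i]; b <- object$pairs$measure_b[i]
    z[a, b] <- z[b, a] <- object$pairs$mean_z[i]
  }
  z
}

#' @export
summary.ord_validity <- function(object, ...) {
  an <- do.call(rbind, lapply(object$anova, function(a) {
    data.frame(measure = a$measure, f = a$f, df_trial = a$df_trial,
               df_error = a$df_error, p = a$p)
  }))
  rownames(an) <- NULL
  structure(list(pairs = object$pairs, anova = an,
                 n_participants = object$n_participants,
                 n_trials = nrow(object$table)),
            class = "summary.ord_validity")
}

#' @export
print.summary.ord_validity <- function(x, digits = 2, ...) {
  cat(sprintf("Convergent-validity summary (%d participants, %d trial rows)\n\n",
              x$n_participants, x$n_trials))
  cat("Pairwise mean Fisher z:\n")
  p <- x$pairs
  print(data.frame(pair = paste(p$measure_a, p$measure_b, sep = " ~ "),
                   mean_z = round(p$mean_z, digits),
                   ci = sprintf("(%.*f, %.*f)", digits, p$ci_low, digits,
                                p$ci_high),
                   t = round(p$t, 2), df = p$df,
                   p = format.pval(p$p, digits = 3), sig = .stars(p$p)),
        row.names = FALSE, right = FALSE)
  cat("\nTrial effect (one-way repeated-measures ANOVA):\n")
  a <- x$anova
  print(data.frame(measure = a$measure,
                   F = round(a$f, 2),
                   df = sprintf("(%d, %d)", a$df_trial, a$df_error),
                   p = format.pval(a$p, digits = 3), sig = .stars(a$p)),
        row.names = FALSE, right = FALSE)
  invisible(x)
}

#' Plot a validity fit
#'
#' `which = "time_course"` draws the per-trial group mean with standard-error
#' bars for each measure (the drowsiness time course over the eight
#' sessions); `which = "pairs"` draws the mean Fisher-z for each measure pair
#' with its confidence interval.
#'
#' @param x An [ord_validity()] fit.
#' @param which `"time_course"` or `"pairs"`.
#' @param ... Passed to the underlying plotting calls.
#' @return `x`, invisibly.
#' @export
plot.ord_validity <- function(x, which = c("time_course", "pairs"), ...) {
  which <- match.arg(which)
  if (which == "time_course") {
    op <- graphics::par(mfrow = c(ceiling(length(x$measures) / 2), 2),
                        mar = c(4, 4, 2, 1))
    on.exit(graphics::par(op))
    for (m in x$measures) {
      tc <- x$time_course[[m]]
      graphics::plot(tc$trial_order, tc$mean, type = "b", pch = 16,
                     xlab = "trial order", ylab = m, main = m, ...)
      graphics::arrows(tc$trial_order, tc$mean - tc$se,
                       tc$trial_order, tc$mean + tc$se,
                       angle = 90, code = 3, length = 0.02)
    }
  } else {
    p <- x$pairs
    lab <- paste(p$measure_a, p$measure_b, sep = "~")
    op <- graphics::par(mar = c(4, 9, 2, 1))
    on.exit(graphics::par(op))
    graphics::plot(p$mean_z, seq_len(nrow(p)), xlim = range(c(0, p$ci_low,
                                                              p$ci_high)),
                   yaxt = "n", xlab = "mean Fisher z", ylab = "", pch = 16,
                   main = "pairwise convergent validity", ...)
    graphics::axis(2, at = seq_len(nrow(p)), labels = lab, las = 2,
                   cex.axis = 0.7)
    graphics::segments(p$ci_low, seq_len(nrow(p)), p$ci_high)
    graphics::abline(v = 0, lty = 2)
  }
  invisible(x)
}
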