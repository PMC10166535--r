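#' Fisher z-transformation of a correlation coefficient
#'
#' `z = atanh(r) = 0.5 * log((1 + r) / (1 - r))`, the variance-stabilizing
#' map used to average and test correlation coefficients.  Correlations with
#' `|r| >= 1 - 1e-6` (numerically perfect) are clipped to `1 - 1e-6` with a
#' warning so the transform stays finite.
#'
#' @param r Numeric vector of correlations, `|r| <= 1`.
#' @return `z` values of the same length.
#' @export
#' @examples
#' fisher_z(0.9)  # 0.5 * log(19) = 1.4722
fisher_z <- function(r) {
  if (any(abs(r) > 1, na.rm = TRUE)) stop("correlation outside [-1, 1]")
  clip <- !is.na(r) & abs(r) >= 1 - 1e-6
  if (any(clip)) {
    warning(sum(clip), " correlation(s) at |r| >= 1 - 1e-6 clipped before atanh")
    r[clip] <- sign(r[clip]) * (1 - 1e-6)
  }
  atanh(r)
}

#' Per-participant Pearson correlations between all measure pairs
#'
#' For each participant, Pearson's r between every unordered pair of the
#' seven drowsiness measures, computed across that participant's trials.
#' Trials missing either value of a pair are dropped (pairwise-complete); a
#' pair with fewer than `min_trials` complete trials, or with a constant
#' measure, yields `NA` with a diagnostic message attribute.
#'
#' @param tab A measure table (see [assemble_measure_table()]).
#' @param measures Character vector of measure columns (defaults to all
#'   seven).
#' @param min_trials Minimum complete trials per pair (default 3).
#' @return A `data.frame` with columns `participant_id`, `measure_a`,
#'   `measure_b`, `n_trials`, `r`.
#' @export
participant_correlations <- function(tab, measures = MEASURE_COLS,
                                     min_trials = 3) {
  stopifnot(all(measures %in% names(tab)), length(measures) >= 2)
  cmb <- utils::combn(measures, 2)
  ids <- unique(tab$participant_id)
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    d <- tab[tab$participant_id == ids[i], , drop = FALSE]
    r <- n <- numeric(ncol(cmb))
    for (k in seq_len(ncol(cmb))) {
      x <- d[[cmb[1, k]]]; y <- d[[cmb[2, k]]]
      ok <- !is.na(x) & !is.na(y)
      n[k] <- sum(ok)
      r[k] <- if (n[k] < min_trials || stats::sd(x[ok]) == 0 ||
                  stats::sd(y[ok]) == 0) {
        NA_real_
      } else {
        stats::cor(x[ok], y[ok])
      }
    }
    out[[i]] <- data.frame(participant_id = ids[i],
                           measure_a = cmb[1, ], measure_b = cmb[2, ],
                           n_trials = n, r = r, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' One-sample t-test of Fisher-z values across participants
#'
#' Tests whether the mean transformed correlation across participants
#' differs from zero: `t = mean(z) / (sd(z) / sqrt(n))` with `n - 1` degrees
#' of freedom, two-sided p from the t distribution, and the matching 95%
#' confidence interval `mean +/- t_{0.975, n-1} * sd / sqrt(n)`.
#'
#' @param z Numeric vector of per-participant Fisher-z values (NAs dropped
#'   with a message).
#' @param conf_level Confidence level (default 0.95).
#' @return A list with `mean_z`, `ci_low`, `ci_high`, `t`, `df`, `p`, `n`.
#' @export
#' @examples
#' group_z_test(c(1, 2, 3))  # t = 3.4641, df = 2
group_z_test <- function(z, conf_level = 0.95) {
  drop <- sum(is.na(z))
  z <- z[!is.na(z)]
  if (drop) message(drop, " undefined correlation(s) excluded from the group test")
  n <- length(z)
  if (n < 2) stop("group z-test needs >= 2 participants")
  s <- stats::sd(z)
  if (s == 0) stop("zero variance across participants: t statistic undefined")
  se <- s / sqrt(n)
  m <- mean(z)
  tq <- stats::qt(1 - (1 - conf_level) / 2, df = n - 1)
  t <- m / se
  list(mean_z = m, ci_low = m - tq * se, ci_high = m + tq * se,
       t = t, df = n - 1, p = 2 * stats::pt(-abs(t), df = n - 1), n = n)
}

#' One-way repeated-measures ANOVA over trials
#'
#' Tests whether a measure changes across the 24 trials of the session
#' sequence, with participant as the repeated-measures unit: the classic
#' two-way within-subject decomposition
#' `SS_total = SS_subject + SS_trial + SS_error`, with
#' `F = MS_trial / MS_error`, `df = (T - 1, (T - 1)(n - 1))` and no
#' sphericity correction.  Participants with any missing trial for the
#' measure are dropped with a message.
#'
#' @param tab A measure table.
#' @param measure Measure column name.
#' @return A list of class `"rm_anova"` with `measure`, `f`, `df_trial`,
#'   `df_error`, `p`, `n`, `n_trials`, `ss` (named sums of squares) and
#'   `time_course` (per-trial grand means and standard errors).
#' @export
rm_anova <- function(tab, measure) {
  stopifnot(measure %in% names(tab), "trial_order" %in% names(tab))
  y <- tab[[measure]]
  wide <- tapply(y, list(tab$participant_id, tab$trial_order), mean)
  complete <- stats::complete.cases(wide)
  if (any(!complete)) {
    message(sum(!complete), " participant(s) dropped from the ", measure,
            " ANOVA for incomplete trials")
  }
  m <- wide[complete, , drop = FALSE]
  n <- nrow(m); T <- ncol(m)
  if (n < 2 || T < 2) stop("repeated-measures ANOVA needs >= 2 participants and >= 2 trials")
  grand <- mean(m)
  ss_subject <- T * sum((rowMeans(m) - grand)^2)
  ss_trial <- n * sum((colMeans(m) - grand)^2)
  ss_total <- sum((m - grand)^2)
  ss_error <- ss_total - ss_subject - ss_trial
  df_trial <- T - 1
  df_error <- (T - 1) * (n - 1)
  if (ss_error <= 0) stop("zero error sum of squares: F statistic undefined")
  f <- (ss_trial / df_trial) / (ss_error / df_error)
  structure(list(measure = measure, f = f, df_trial = df_trial,
                 df_error = df_error,
                 p = stats::pf(f, df_trial, df_error, lower.tail = FALSE),
                 n = n, n_trials = T,
                 ss = c(subject = ss_subject, trial = ss_trial,
                        error = ss_error, total = ss_total),
                 time_course = data.frame(
                   trial_order = as.integer(colnames(m)),
                   mean = colMeans(m),
                   se = apply(m, 2, stats::sd) / sqrt(n))),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("RM-ANOVA of %s over %d trials, n = %d: F(%d, %d) = %.2f, p %s\n",
              x$measure, x$n_trials, x$n, x$df_trial, x$df_error, x$f,
              format.pval(x$p, digits = 3)))
  invisible(x)
}

#' Per-trial group mean and standard error of a measure
#'
#' The time-course summary plotted against trial order: for each global
#' trial (1-24), the mean and standard error of the measure across
#' participants.
#'
#' @param tab A measure table.
#' @param measure Measure column name.
#' @return `data.frame` with `trial_order`, `n`, `mean`, `se`.
#' @export
time_course_summary <- function(tab, measure) {
  stopifnot(measure %in% names(tab))
  sp <- split(tab[[measure]], tab$trial_order)
  res <- data.frame(
    trial_order = as.integer(names(sp)),
    n = vapply(sp, function(v) sum(!is.na(v)), integer(1)),
    mean = vapply(sp, function(v) mean(v, na.rm = TRUE), numeric(1)),
    se = vapply(sp, function(v) {
      v <- v[!is.na(v)]
      if (length(v) < 2) return(NA_real_)
      stats::sd(v) / sqrt(length(v))
    }, numeric(1)))
  rownames(res) <- NULL
  res[order(res$trial_order), ]
}
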