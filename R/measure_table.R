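MEASURE_COLS <- c("ord_mean", "kss", "sdlp_cm", "perclos_pct", "sem_pct",
                  "eeg_alpha_power", "eeg_theta_power")

#' Assemble the trial-level measure table
#'
#' Joins per-trial measure values produced by the extraction stages into one
#' row per trial, the table the statistical battery consumes.  Missing
#' measures stay `NA`; they are never imputed.
#'
#' @param trials `data.frame` with key columns `participant_id`, `session`,
#'   `trial` and any subset of the measure columns `ord_mean`, `kss`,
#'   `sdlp_cm`, `perclos_pct`, `sem_pct`, `eeg_alpha_power`,
#'   `eeg_theta_power`.  Alternatively a list of such data.frames, each
#'   carrying some of the measures for the same keys; they are merged on the
#'   key.
#' @return A `data.frame` of class `"measure_table"` with the key columns, a
#'   derived `trial_order` column, and all seven measure columns (NA where a
#'   value was not supplied).  Duplicate keys, or conflicting non-missing
#'   values for the same key and measure, are an error.
#' @export
assemble_measure_table <- function(trials) {
  if (is.data.frame(trials)) trials <- list(trials)
  key_cols <- c("participant_id", "session", "trial")
  pieces <- lapply(trials, function(d) {
    stopifnot(is.data.frame(d), all(key_cols %in% names(d)))
    if (anyDuplicated(d[key_cols])) {
      stop("duplicate (participant, session, trial) keys in input table")
    }
    d
  })
  out <- unique(do.call(rbind, lapply(pieces, function(d) d[key_cols])))
  for (m in MEASURE_COLS) out[[m]] <- NA_real_
  rownames(out) <- NULL
  key_of <- function(d) paste(d$participant_id, d$session, d$trial, sep = "\r")
  ok <- key_of(out)
  for (d in pieces) {
    idx <- match(key_of(d), ok)
    for (m in intersect(names(d), MEASURE_COLS)) {
      new <- as.numeric(d[[m]])
      cur <- out[[m]][idx]
      clash <- !is.na(cur) & !is.na(new) & abs(cur - new) > 1e-9
      if (any(clash)) stop("conflicting values supplied for measure '", m, "'")
      out[[m]][idx] <- ifelse(is.na(new), cur, new)
    }
  }
  out <- out[order(out$participant_id, out$session, out$trial), ]
  rownames(out) <- NULL
  out$trial_order <- 3L * (as.integer(out$session) - 1L) + as.integer(out$trial)
  out <- out[c(key_cols, "trial_order", MEASURE_COLS)]
  validate_measure_table(out)
}

validate_measure_table <- function(tab) {
  chk <- function(col, lo, hi) {
    v <- tab[[col]]
    bad <- !is.na(v) & (v < lo | v > hi)
    if (any(bad)) stop(sprintf("column %s outside [%g, %g] in %d row(s)",
                               col, lo, hi, sum(bad)))
  }
  chk("ord_mean", 1, 5); chk("kss", 1, 9)
  chk("perclos_pct", 0, 100); chk("sem_pct", 0, 100)
  chk("sdlp_cm", 0, Inf)
  chk("eeg_alpha_power", 0, Inf); chk("eeg_theta_power", 0, Inf)
  class(tab) <- unique(c("measure_table", class(tab)))
  tab
}

#' Restrict a measure table to participants with a qualifying KSS range
#'
#' The participant-selection rule of the study design: a participant is kept
#' only if, over all their trials, the number of KSS responses at or above
#' `kss_high` and the number at or below `kss_low` are each at least
#' `kss_min_count` (the "greater than two" criterion read strictly).
#'
#' @param tab A measure table (see [assemble_measure_table()]).
#' @param config An [analysis_config()]; fields `kss_high`, `kss_low`,
#'   `kss_min_count` are used.
#' @return The filtered table (possibly with zero rows).  Idempotent.
#' @export
filter_participants_by_kss_range <- function(tab, config = analysis_config()) {
  stopifnot("kss" %in% names(tab))
  if (nrow(tab) == 0L) return(tab)
  hi <- tapply(tab$kss >= config$kss_high, tab$participant_id, sum)
  lo <- tapply(tab$kss <= config$kss_low, tab$participant_id, sum)
  keep_ids <- names(hi)[hi >= config$kss_min_count & lo >= config$kss_min_count]
  out <- tab[tab$participant_id %in% keep_ids, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a trial-level measure table from delimited text
#'
#' Tolerant reader for the trial table: accepts the package's own column
#' names as well as spreadsheet-style labels (matching is case-insensitive
#' and ignores spaces, punctuation and units), e.g. `"subject ID"`,
#' `"mean ORD"`, `"percentage of time occupied by SEM"`,
#' `"mean EEG alpha power"`.
#'
#' @param path Path to a comma- or tab-separated text file with a header row.
#' @return A measure table `data.frame`.
#' @export
read_trial_table <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) == 1L) d <- utils::read.delim(path, check.names = FALSE,
                                            stringsAsFactors = FALSE)
  canon <- function(x) gsub("[^a-z0-9]", "", tolower(x))
  alias <- list(
    participant_id = c("participantid", "subjectid", "subject", "participant", "id"),
    session = c("session", "sessionid", "sessionindex"),
    trial = c("trial", "trialid", "trialindex", "trialinsession"),
    ord_mean = c("ordmean", "meanord", "ord", "ordscore"),
    kss = c("kss", "ksslevel", "kssresponse"),
    sdlp_cm = c("sdlpcm", "sdlp"),
    perclos_pct = c("perclospct", "perclos", "perclospercent"),
    sem_pct = c("sempct", "sem", "percentageoftimeoccupiedbysem",
                "percentsem", "semtimepct"),
    eeg_alpha_power = c("eegalphapower", "meaneegalphapower", "alphapower",
                        "alpha"),
    eeg_theta_power = c("eegthetapower", "meaneegthetapower", "thetapower",
                        "theta"))
  got <- canon(names(d))
  out <- data.frame(row.names = seq_len(nrow(d)))
  for (nm in names(alias)) {
    hit <- which(got %in% alias[[nm]])
    if (length(hit)) out[[nm]] <- d[[hit[1]]]
  }
  need <- c("participant_id", "session", "trial")
  if (!all(need %in% names(out))) {
    stop("trial table at '", path, "' lacks key column(s): ",
         paste(setdiff(need, names(out)), collapse = ", "))
  }
  out$participant_id <- as.character(out$participant_id)
  out$session <- as.integer(out$session)
  out$trial <- as.integer(out$trial)
  for (m in MEASURE_COLS) {
    out[[m]] <- if (m %in% names(out)) as.numeric(out[[m]]) else NA_real_
  }
  out$trial_order <- 3L * (out$session - 1L) + out$trial
  out <- out[c(need, "trial_order", MEASURE_COLS)]
  validate_measure_table(out)
}

#' Write a trial-level measure table
#' @param tab A measure table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(tab, path) {
  utils::write.csv(as.data.frame(tab)[c("participant_id", "session", "trial",
                                        MEASURE_COLS)],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
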