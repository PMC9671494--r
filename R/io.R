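# Plain-text interchange formats: two-column signal files and TSV event
# tables. All writers are deterministic (fixed column order, fixed digits) so
# that repeated pipeline runs with the same seed are bit-identical.

#' Read a two-column (time_ms, value) signal file
#'
#' @param path text file with header `time_ms\tvalue` (TSV).
#' @return `ecg_signal`; the sampling rate is inferred from the median time
#'   step and must be regular to within 1%.
#' @export
read_signal_file <- function(path) {
  d <- utils::read.delim(path, header = TRUE)
  if (!all(c("time_ms", "value") %in% names(d))) {
    stop("signal file must have columns `time_ms` and `value`")
  }
  dt <- diff(d$time_ms)
  if (max(abs(dt - stats::median(dt))) > 0.01 * stats::median(dt)) {
    stop("signal file is not regularly sampled")
  }
  ecg_signal(d$value, 1000 / stats::median(dt), t0 = d$time_ms[1])
}

#' Write a sampled signal as a two-column TSV
#' @param signal an `ecg_signal`.
#' @param path output path.
#' @export
write_signal_file <- function(signal, path) {
  d <- data.frame(time_ms = sample_times(signal),
                  value = signal$samples)
  write_tsv(d, path)
}

# deterministic TSV writer: numbers at 15 significant digits, "." decimal
write_tsv <- function(d, path) {
  num <- vapply(d, is.numeric, logical(1))
  d[num] <- lapply(d[num], function(x) {
    ifelse(is.na(x), "NA", trimws(formatC(x, digits = 15, format = "g")))
  })
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
}

#' Write beat tables (one row per beat) as TSV
#'
#' Columns: participant, r_time, t_peak, t_end, qc_flag (pass/fail:reason).
#'
#' @param beats named list of `beat_series` (or a single one).
#' @param path output path.
#' @export
write_beats_tsv <- function(beats, path) {
  if (inherits(beats, "beat_series")) beats <- list(P1 = beats)
  rows <- do.call(rbind, Map(function(id, b) {
    data.frame(participant = id, r_time = b$r_time, t_peak = b$t_peak,
               t_end = b$t_end,
               qc_flag = ifelse(b$qc_pass, "pass",
                                paste0("fail:", b$qc_reason)))
  }, names(beats), beats))
  write_tsv(rows, path)
}

#' Write a trial table as TSV
#'
#' Columns: participant, condition, level, onset_ms, offset_ms, correct,
#' excluded, reason.
#'
#' @param trials trial data.frame.
#' @param path output path.
#' @export
write_trials_tsv <- function(trials, path) {
  d <- data.frame(participant = trials$participant,
                  condition = trials$condition,
                  level = trials$level,
                  onset_ms = trials$onset,
                  offset_ms = trials$offset,
                  correct = trials$correct)
  d$excluded <- if ("excluded" %in% names(trials)) trials$excluded else NA
  d$reason <- if ("exclusion_reason" %in% names(trials)) {
    trials$exclusion_reason
  } else NA_character_
  write_tsv(d, path)
}

#' Import beat and trial event tables (bypassing signal detection)
#'
#' Validates the TSV schemas written by [write_beats_tsv()] /
#' [write_trials_tsv()]; schema violations are reported with row numbers,
#' and the import hard-fails when more than `max_bad` of rows are malformed.
#'
#' @param beats_path beat table TSV.
#' @param trials_path trial table TSV.
#' @param max_bad maximum tolerated fraction of malformed rows (default 0.01).
#' @return list with `beats` (named list of `beat_series`), `trials`
#'   (data.frame with `onset`, `offset`, `hold`, ... columns) and `errors`
#'   (character vector describing rejected rows).
#' @export
import_event_tables <- function(beats_path, trials_path, max_bad = 0.01) {
  need_cols <- function(d, cols, what) {
    miss <- setdiff(cols, names(d))
    if (length(miss)) {
      stop(sprintf("%s: schema error, missing column(s) %s", what,
                   paste(miss, collapse = ", ")))
    }
  }
  bt <- utils::read.delim(beats_path, header = TRUE,
                          colClasses = c(participant = "character"))
  need_cols(bt, c("participant", "r_time", "t_peak", "t_end", "qc_flag"),
            "beat table")
  tr <- utils::read.delim(trials_path, header = TRUE,
                          colClasses = c(participant = "character",
                                         level = "character"))
  need_cols(tr, c("participant", "condition", "level", "onset_ms",
                  "offset_ms", "correct"), "trial table")
  errors <- character(0)
  bad <- which(!is.finite(tr$onset_ms) | !is.finite(tr$offset_ms) |
                 tr$onset_ms < 0 | tr$offset_ms <= tr$onset_ms)
  if (length(bad)) {
    errors <- c(errors, sprintf("trial row %d: invalid onset/offset", bad))
    tr <- tr[-bad, ]
  }
  badb <- which(!is.finite(bt$r_time))
  if (length(badb)) {
    errors <- c(errors, sprintf("beat row %d: invalid r_time", badb))
    bt <- bt[-badb, ]
  }
  n_all <- nrow(tr) + nrow(bt) + length(errors)
  if (length(errors) > max_bad * n_all) {
    stop(sprintf("import aborted: %d malformed rows (> %.0f%%):\n%s",
                 length(errors), 100 * max_bad,
                 paste(utils::head(errors, 10), collapse = "\n")))
  }
  beats <- lapply(split(bt, bt$participant), function(b) {
    b <- b[order(b$r_time), ]
    reason <- ifelse(startsWith(b$qc_flag, "fail:"),
                     sub("^fail:", "", b$qc_flag), NA_character_)
    beat_series(b$r_time, b$t_end, t_peak = b$t_peak, qc_reason = reason)
  })
  trials <- data.frame(participant = tr$participant,
                       condition = tr$condition, level = tr$level,
                       onset = tr$onset_ms, offset = tr$offset_ms,
                       hold = tr$offset_ms - tr$onset_ms,
                       correct = as.logical(tr$correct),
                       stringsAsFactors = FALSE)
  if ("excluded" %in% names(tr)) {
    trials$excluded <- as.logical(tr$excluded)
    trials$exclusion_reason <- if ("reason" %in% names(tr)) {
      as.character(tr$reason)
    } else NA_character_
  }
  list(beats = beats, trials = trials, errors = errors)
}

#' Read a trial table TSV (without a beat table)
#' @param path trial table written by [write_trials_tsv()].
#' @return trial data.frame with `onset`, `offset`, `hold` columns.
#' @export
read_trials_tsv <- function(path) {
  tr <- utils::read.delim(path, header = TRUE,
                          colClasses = c(participant = "character",
                                         level = "character"))
  need <- c("participant", "condition", "level", "onset_ms", "offset_ms",
            "correct")
  miss <- setdiff(need, names(tr))
  if (length(miss)) {
    stop(sprintf("trial table: schema error, missing column(s) %s",
                 paste(miss, collapse = ", ")))
  }
  data.frame(participant = tr$participant, condition = tr$condition,
             level = tr$level, onset = tr$onset_ms, offset = tr$offset_ms,
             hold = tr$offset_ms - tr$onset_ms,
             correct = as.logical(tr$correct), stringsAsFactors = FALSE)
}
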