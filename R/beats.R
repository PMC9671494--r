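#' Beat series container
#'
#' An ordered table of cardiac cycles. Each row holds one beat's R-peak time,
#' T-peak time and T-wave end time (all in ms from recording start) plus a QC
#' flag. The interbeat interval (IBI) of cycle i is `r_time[i+1] - r_time[i]`;
#' cycles are half-open intervals `[R_i, R_{i+1})`. The last row has no IBI.
#'
#' @param r_time strictly increasing numeric vector of R-peak times (ms).
#' @param t_end numeric vector of T-wave end times (ms), same length; may
#'   contain `NA` for beats where delineation failed.
#' @param t_peak optional numeric vector of T-peak times (ms); when missing it
#'   is filled at 62% of the R-to-T-end interval (only used for rendering).
#' @param qc_reason optional character vector of pre-existing failure reasons
#'   (`NA` = none).
#' @return data.frame of class `"beat_series"` with columns `r_time`,
#'   `t_peak`, `t_end`, `ibi`, `qc_pass`, `qc_reason`, and attribute
#'   `median_rt` (median R-to-T-end interval over passing beats).
#' @export
beat_series <- function(r_time, t_end, t_peak = NULL, qc_reason = NULL) {
  n <- length(r_time)
  if (length(t_end) != n) stop("`r_time` and `t_end` must have equal length")
  if (n > 1 && any(diff(r_time) <= 0)) {
    stop("`r_time` must be strictly increasing")
  }
  if (is.null(t_peak)) t_peak <- r_time + 0.62 * (t_end - r_time)
  if (is.null(qc_reason)) qc_reason <- rep(NA_character_, n)
  # snap event times to a dyadic 2^-10 ms (~1 us) grid: far below any
  # measurement resolution, and it makes window arithmetic (differences of
  # beat times) exact in floating point, so the equal-length systole and
  # diastole windows are equal *exactly*
  snap <- function(x) round(x * 1024) / 1024
  r_time <- snap(r_time); t_end <- snap(t_end); t_peak <- snap(t_peak)
  ibi <- if (n) c(diff(r_time), NA_real_) else numeric(0)
  next_r <- if (n) c(r_time[-1], NA_real_) else numeric(0)

  qc_pass <- rep(TRUE, n)
  reason <- qc_reason
  bad_na <- is.na(t_end)
  bad_order <- !bad_na & (t_end <= r_time |
                            (!is.na(t_peak) & (t_peak <= r_time | t_end < t_peak)) |
                            (!is.na(next_r) & t_end >= next_r))
  reason[bad_na & is.na(reason)] <- "t-end not found"
  reason[bad_order & is.na(reason)] <- "event ordering violated"
  qc_pass <- is.na(reason)

  out <- data.frame(r_time = r_time, t_peak = t_peak, t_end = t_end,
                    ibi = ibi, qc_pass = qc_pass, qc_reason = reason)
  class(out) <- c("beat_series", "data.frame")
  rt <- out$t_end[out$qc_pass] - out$r_time[out$qc_pass]
  attr(out, "median_rt") <- if (length(rt)) stats::median(rt) else NA_real_
  out
}

#' Assemble aligned R-peak and T-end lists into a beat series
#'
#' Beats violating the within-cycle ordering `R < T-peak < T-end < next R` are
#' flagged as QC failures rather than dropped, so that downstream trial
#' exclusion can see them.
#'
#' @param r_peaks numeric vector of R-peak times (ms).
#' @param t_ends numeric vector of T-end times (ms), aligned with `r_peaks`.
#' @param t_peaks optional aligned T-peak times (ms).
#' @param qc_reason optional aligned character vector of upstream failures.
#' @return `beat_series`.
#' @export
assemble_beats <- function(r_peaks, t_ends, t_peaks = NULL, qc_reason = NULL) {
  beat_series(r_peaks, t_ends, t_peak = t_peaks, qc_reason = qc_reason)
}

#' R-to-T-end temporal consistency filter
#'
#' Beats whose R-to-T-end interval deviates from the participant's median
#' interval by more than `factor * median` are flagged as QC failures.
#' Trials overlapping flagged beats are later excluded by
#' [apply_exclusions()].
#'
#' @param beats a `beat_series`.
#' @param factor positive deviation multiplier (default 1.5).
#' @return the `beat_series` with updated flags and `median_rt` attribute.
#' @export
rt_consistency_filter <- function(beats, factor = 1.5) {
  stopifnot(inherits(beats, "beat_series"))
  if (!is.numeric(factor) || factor <= 0) stop("`factor` must be > 0")
  rt <- beats$t_end - beats$r_time
  med <- stats::median(rt[beats$qc_pass], na.rm = TRUE)
  bad <- beats$qc_pass & !is.na(rt) & abs(rt - med) > factor * med
  beats$qc_pass[bad] <- FALSE
  beats$qc_reason[bad] <- "rt_inconsistent"
  if (sum(beats$qc_pass) < 3L) {
    stop("recording rejected: fewer than 3 beats pass the R-T consistency filter")
  }
  attr(beats, "median_rt") <-
    stats::median(beats$t_end[beats$qc_pass] - beats$r_time[beats$qc_pass])
  beats
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("<beat_series> %d beats, %d passing QC, median R-T %.1f ms\n",
              nrow(x), sum(x$qc_pass), attr(x, "median_rt")))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("... %d more beats\n", nrow(x) - 6L))
  invisible(x)
}
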