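#' Circular phase of events within their cardiac cycle
#'
#' For an event at time `t` inside cycle `[R_i, R_{i+1})` the phase angle is
#' `360 * (t - R_i) / (R_{i+1} - R_i)` degrees, so 0 marks the R-peak opening
#' the cycle and the angle grows piecewise-linearly to 360 at the next R.
#'
#' @param t numeric vector of event times (ms).
#' @param beats a `beat_series`. Events outside `[first R, last R)` get `NA`
#'   angle and cycle (dropped downstream, with the count logged as an
#'   attribute `n_dropped`).
#' @return data.frame with `event_time`, `cycle_index`, `angle` (degrees in
#'   `[0, 360)`).
#' @export
phase_of_event <- function(t, beats) {
  stopifnot(inherits(beats, "beat_series"))
  r <- beats$r_time
  n <- length(r)
  i <- findInterval(t, r)
  ok <- i >= 1L & i < n
  angle <- rep(NA_real_, length(t))
  angle[ok] <- 360 * (t[ok] - r[i[ok]]) / (r[i[ok] + 1] - r[i[ok]])
  i[!ok] <- NA_integer_
  out <- data.frame(event_time = t, cycle_index = i, angle = angle)
  attr(out, "n_dropped") <- sum(!ok)
  out
}

#' Circular mean phase of a stationary hold
#'
#' Evaluates the event phase at the midpoints of a regular grid (1 ms bins
#' by default, the usual acquisition resolution) across `[onset, offset)` —
#' which often spans more than one heartbeat — and takes the circular mean
#' of the sampled angles. Midpoint sampling makes the estimate exact for
#' symmetric arcs and second-order accurate, so finer grids agree to well
#' under 0.1 degrees. A hold covering whole cycles has a numerically zero
#' resultant; below `1e-9` the mean is reported `NA`.
#'
#' @param onset,offset hold start and end times (ms), `offset > onset`.
#' @param beats a `beat_series` covering the hold.
#' @param grid sampling step in ms (default 1; finer grids agree to < 0.1 deg).
#' @return list with `mean_deg` (`NA` when undefined), `resultant`, `n_grid`.
#' @export
mean_hold_phase <- function(onset, offset, beats, grid = 1) {
  if (offset <= onset) stop("`offset` must exceed `onset`")
  tg <- seq(onset + grid / 2, offset, by = grid)
  ph <- phase_of_event(tg, beats)
  ang <- ph$angle[!is.na(ph$angle)]
  if (!length(ang)) {
    return(list(mean_deg = NA_real_, resultant = NA_real_, n_grid = 0L))
  }
  cm <- circular_mean(ang)
  if (cm$resultant < 1e-9) cm$mean_deg <- NA_real_
  list(mean_deg = cm$mean_deg, resultant = cm$resultant, n_grid = cm$n)
}

#' Equal-length systole and diastole windows per beat
#'
#' Systole is the interval from the R-peak to the T-wave end,
#' `[R_i, Tend_i)`. To equate the probability of an event falling in either
#' phase, the diastole window has the *same length* and is anchored at the
#' end of the cycle: `[R_{i+1} - (Tend_i - R_i), R_{i+1})`. The mid-cycle gap
#' between the two windows belongs to neither ("unassigned"). A cycle too
#' short to fit both windows is QC-failed.
#'
#' @param beats a `beat_series`.
#' @return data.frame, one row per cycle with a following beat: `cycle`,
#'   `sys_lo`, `sys_hi`, `dia_lo`, `dia_hi`, `usable` (beat passes QC and the
#'   windows do not overlap).
#' @export
build_phase_windows <- function(beats) {
  stopifnot(inherits(beats, "beat_series"))
  n <- nrow(beats)
  if (n < 2) stop("need at least 2 beats to build phase windows")
  i <- seq_len(n - 1L)
  r <- beats$r_time[i]
  next_r <- beats$r_time[i + 1L]
  t_end <- beats$t_end[i]
  len <- t_end - r
  dia_lo <- next_r - len
  usable <- beats$qc_pass[i] & !is.na(t_end) & t_end < dia_lo
  data.frame(cycle = i, sys_lo = r, sys_hi = t_end,
             dia_lo = dia_lo, dia_hi = next_r, usable = usable)
}

#' Classify events into systole / diastole / unassigned windows
#'
#' @param t numeric vector of event times (ms).
#' @param beats a `beat_series`.
#' @return character vector: `"systole"`, `"diastole"`, `"unassigned"`, or
#'   `NA` for events outside beat coverage or in QC-failed cycles.
#' @export
classify_event <- function(t, beats) {
  win <- build_phase_windows(beats)
  ph <- phase_of_event(t, beats)
  out <- rep(NA_character_, length(t))
  i <- ph$cycle_index
  ok <- !is.na(i) & i <= nrow(win)
  okk <- which(ok)[win$usable[i[ok]]]
  w <- win[i[okk], ]
  lab <- ifelse(t[okk] >= w$sys_lo & t[okk] < w$sys_hi, "systole",
                ifelse(t[okk] >= w$dia_lo & t[okk] < w$dia_hi, "diastole",
                       "unassigned"))
  out[okk] <- lab
  out
}

#' Interbeat intervals around a touch onset
#'
#' Returns the IBI of the cycle containing the onset (position 0) and of the
#' two preceding and two following heartbeats, decomposed into the electrical
#' systole length and the diastole remainder (`IBI - systole`; the full
#' remainder, not the equal-length event window, because this analysis
#' concerns phase *durations*).
#'
#' @param onset onset time (ms).
#' @param beats a `beat_series`. Needs 2 complete cycles before and after
#'   the onset's cycle; otherwise the trial is dropped from this analysis
#'   (`NULL` returned).
#' @return data.frame with `position` (-2..2), `ibi`, `systole`, `diastole`,
#'   or `NULL` when context is insufficient.
#' @export
ibi_context <- function(onset, beats) {
  stopifnot(inherits(beats, "beat_series"))
  r <- beats$r_time
  i <- findInterval(onset, r)
  n <- length(r)
  if (i < 3L || i + 3L > n) return(NULL)
  pos <- (-2):2
  idx <- i + pos
  ibi <- r[idx + 1L] - r[idx]
  sys <- beats$t_end[idx] - r[idx]
  data.frame(position = pos, ibi = ibi, systole = sys, diastole = ibi - sys)
}

#' Annotate trials with cardiac-phase information
#'
#' Adds, per trial: onset/offset angles and window labels, and (optionally,
#' it is the expensive part) the circular mean phase of the stationary hold.
#'
#' @param trials trial data.frame (needs `onset`, `offset`; `participant`
#'   optional for the single-series form).
#' @param beats a `beat_series` (single participant) or a named list of beat
#'   series keyed by participant.
#' @param events which annotations to compute: subset of
#'   `c("onset", "offset", "hold")`.
#' @param hold_grid grid step (ms) for the hold circular mean.
#' @return `trials` with columns `onset_angle`, `onset_window`,
#'   `offset_angle`, `offset_window`, `hold_angle`, `hold_resultant`
#'   (requested ones filled, others NA).
#' @export
annotate_phases <- function(trials, beats,
                            events = c("onset", "offset", "hold"),
                            hold_grid = 1) {
  events <- match.arg(events, several.ok = TRUE)
  if (inherits(beats, "beat_series")) {
    ids <- if ("participant" %in% names(trials)) unique(trials$participant) else "P1"
    if (length(ids) > 1) stop("multiple participants but a single beat series")
    beats <- stats::setNames(list(beats), ids)
    if (!"participant" %in% names(trials)) trials$participant <- ids
  }
  trials$onset_angle <- trials$offset_angle <- NA_real_
  trials$onset_window <- trials$offset_window <- NA_character_
  trials$hold_angle <- trials$hold_resultant <- NA_real_
  for (id in unique(trials$participant)) {
    rows <- which(trials$participant == id)
    b <- beats[[id]]
    if (is.null(b)) stop(sprintf("no beat series for participant %s", id))
    if ("onset" %in% events) {
      trials$onset_angle[rows] <- phase_of_event(trials$onset[rows], b)$angle
      trials$onset_window[rows] <- classify_event(trials$onset[rows], b)
    }
    if ("offset" %in% events) {
      trials$offset_angle[rows] <- phase_of_event(trials$offset[rows], b)$angle
      trials$offset_window[rows] <- classify_event(trials$offset[rows], b)
    }
    if ("hold" %in% events) {
      for (k in rows) {
        mh <- mean_hold_phase(trials$onset[k], trials$offset[k], b,
                              grid = hold_grid)
        trials$hold_angle[k] <- mh$mean_deg
        trials$hold_resultant[k] <- mh$resultant
      }
    }
  }
  trials
}

#' IBI context table for many trials
#'
#' @param trials trial data.frame with `participant` and `onset` columns.
#' @param beats named list of `beat_series`.
#' @param condition optional condition filter.
#' @return stacked data.frame (`participant`, `trial`, `position`, `ibi`,
#'   `systole`, `diastole`); trials near recording edges are dropped and
#'   counted in attribute `n_dropped`.
#' @export
ibi_contexts <- function(trials, beats, condition = NULL) {
  if (!is.null(condition)) trials <- trials[trials$condition %in% condition, ]
  out <- vector("list", nrow(trials))
  dropped <- 0L
  for (k in seq_len(nrow(trials))) {
    ctx <- ibi_context(trials$onset[k], beats[[trials$participant[k]]])
    if (is.null(ctx)) { dropped <- dropped + 1L; next }
    ctx$participant <- trials$participant[k]
    ctx$trial <- k
    out[[k]] <- ctx
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  attr(res, "n_dropped") <- dropped
  res
}
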