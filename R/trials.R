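#' Parse the touch pulse channel into trials
#'
#' The acquisition encodes each touch as a continuous pulse whose amplitude
#' codes the stimulus level (seven grating widths plus the flat control).
#' A trial spans each maximal run of samples departing from zero; runs
#' separated by less than `merge_gap` ms are collapsed into a single
#' multi-contact event (flagged, since trials with consecutive contacts are
#' excluded). The level is decoded from the plateau (median) amplitude,
#' matched to the nearest entry of `amplitude_map` within `tol`.
#'
#' @param pulse an `ecg_signal`-style sampled series (`samples`,
#'   `sampling_rate`, `t0`) carrying the pulse channel.
#' @param amplitude_map named numeric vector mapping levels (`"1"`..`"7"`,
#'   `"control"`) to pulse amplitudes; must be injective.
#' @param tol absolute amplitude tolerance; defaults to 40% of the smallest
#'   spacing between mapped amplitudes.
#' @param merge_gap gap (ms) under which consecutive runs merge, default 150.
#' @return trial data.frame: `condition`, `level` (`NA` when unknown),
#'   `onset`, `offset`, `hold`, `correct` (NA; filled by the caller from the
#'   response log), `n_contacts`, `flag_reason` (`NA`, `multiple_contacts` or
#'   `unknown_level`). All-zero channels give zero rows.
#' @export
parse_pulse_channel <- function(pulse, amplitude_map, tol = NULL,
                                merge_gap = 150) {
  if (anyDuplicated(amplitude_map)) stop("`amplitude_map` must be injective")
  if (is.null(tol)) {
    tol <- if (length(amplitude_map) > 1) {
      0.4 * min(diff(sort(amplitude_map)))
    } else 0.4 * abs(amplitude_map[[1]])
  }
  v <- pulse$samples
  dt <- 1000 / pulse$sampling_rate
  tt <- pulse$t0 + (seq_along(v) - 1) * dt
  eps <- 0.05 * min(abs(amplitude_map))
  act <- abs(v) > eps
  empty <- data.frame(condition = character(0), level = character(0),
                      onset = numeric(0), offset = numeric(0),
                      hold = numeric(0), correct = logical(0),
                      n_contacts = integer(0), flag_reason = character(0))
  if (!any(act)) return(empty)
  rl <- rle(act)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  runs <- data.frame(start = starts[rl$values], end = ends[rl$values])
  # merge runs separated by < merge_gap into multi-contact events
  ev_start <- runs$start[1]; ev_end <- runs$end[1]; ev_n <- 1L
  events <- list()
  push <- function() {
    events[[length(events) + 1L]] <<- c(ev_start, ev_end, ev_n)
  }
  if (nrow(runs) > 1) {
    for (j in 2:nrow(runs)) {
      gap_ms <- (runs$start[j] - ev_end - 1L) * dt
      if (gap_ms < merge_gap) {
        ev_end <- runs$end[j]; ev_n <- ev_n + 1L
      } else {
        push()
        ev_start <- runs$start[j]; ev_end <- runs$end[j]; ev_n <- 1L
      }
    }
  }
  push()
  ev <- do.call(rbind, events)
  level <- character(nrow(ev)); reason <- rep(NA_character_, nrow(ev))
  for (j in seq_len(nrow(ev))) {
    plateau <- stats::median(v[ev[j, 1]:ev[j, 2]])
    d <- abs(amplitude_map - plateau)
    if (min(d) <= tol) {
      level[j] <- names(amplitude_map)[which.min(d)]
    } else {
      level[j] <- NA_character_
      reason[j] <- "unknown_level"
    }
  }
  reason[ev[, 3] > 1L] <- "multiple_contacts"  # takes precedence
  onset <- tt[ev[, 1]]
  offset <- tt[ev[, 2]] + dt   # return-to-zero time
  data.frame(condition = ifelse(is.na(level), NA_character_,
                                ifelse(level == "control", "control", "gratings")),
             level = level, onset = onset, offset = offset,
             hold = offset - onset, correct = NA,
             n_contacts = as.integer(ev[, 3]), flag_reason = reason,
             stringsAsFactors = FALSE)
}

#' Apply trial exclusion rules
#'
#' Flags (never deletes) trials, testing the rules in this fixed order and
#' recording the first matching reason: `multiple_contacts`,
#' `unknown_level`, `response_before_release`, `too_short` (< 100 ms),
#' `too_long` (> 5000 ms), `duration_outlier` (beyond `sd_mult` SDs of the
#' participant's mean duration, computed per participant x condition over
#' the trials surviving the fixed-bound rules — pooled across difficulty
#' levels by default), and `beat_qc` (the touch overlaps a QC-failed beat or
#' falls outside beat coverage).
#'
#' @param trials trial data.frame (`participant` optional; added if missing).
#' @param beats optional `beat_series` or named list of beat series, already
#'   passed through [rt_consistency_filter()].
#' @param response_times optional numeric vector (ms) of verbal-response
#'   times aligned with `trials`; a response before the touch offset excludes
#'   the trial.
#' @param bounds fixed hold-duration bounds in ms, default `c(100, 5000)`.
#' @param sd_mult outlier multiplier, default 3.
#' @param sd_pooling `"pooled"` (default: one mean/SD per participant x
#'   condition) or `"per_level"`.
#' @return `trials` with `excluded` and `exclusion_reason` columns; the
#'   retained fraction is stored in attribute `retained`.
#' @export
apply_exclusions <- function(trials, beats = NULL, response_times = NULL,
                             bounds = c(100, 5000), sd_mult = 3,
                             sd_pooling = c("pooled", "per_level")) {
  sd_pooling <- match.arg(sd_pooling)
  if (!"participant" %in% names(trials)) trials$participant <- "P1"
  n <- nrow(trials)
  reason <- rep(NA_character_, n)
  if ("flag_reason" %in% names(trials)) reason <- trials$flag_reason
  if ("n_contacts" %in% names(trials)) {
    reason[is.na(reason) & trials$n_contacts > 1L] <- "multiple_contacts"
  }
  if (!is.null(response_times)) {
    hit <- is.na(reason) & !is.na(response_times) &
      response_times < trials$offset
    reason[hit] <- "response_before_release"
  }
  reason[is.na(reason) & trials$hold < bounds[1]] <- "too_short"
  reason[is.na(reason) & trials$hold > bounds[2]] <- "too_long"

  grp <- if (sd_pooling == "pooled") {
    interaction(trials$participant, trials$condition, drop = TRUE)
  } else {
    interaction(trials$participant, trials$condition, trials$level, drop = TRUE)
  }
  for (g in levels(grp)) {
    rows <- which(grp == g & is.na(reason))
    if (length(rows) < 3) next
    m <- mean(trials$hold[rows]); s <- stats::sd(trials$hold[rows])
    if (is.na(s) || s == 0) next
    out <- rows[abs(trials$hold[rows] - m) > sd_mult * s]
    reason[out] <- "duration_outlier"
  }

  if (!is.null(beats)) {
    if (inherits(beats, "beat_series")) {
      beats <- stats::setNames(list(beats), unique(trials$participant)[1])
    }
    for (id in unique(trials$participant)) {
      b <- beats[[id]]
      if (is.null(b)) next
      rows <- which(trials$participant == id & is.na(reason))
      if (!length(rows)) next
      r <- b$r_time
      bad_lo <- r[which(!b$qc_pass)]
      bad_hi <- c(r, Inf)[which(!b$qc_pass) + 1L]
      for (k in rows) {
        on <- trials$onset[k]; off <- trials$offset[k]
        if (on < r[1] || off >= r[length(r)]) {
          reason[k] <- "beat_qc"
        } else if (length(bad_lo) &&
                   any(on < bad_hi & off > bad_lo)) {
          reason[k] <- "beat_qc"
        }
      }
    }
  }
  trials$excluded <- !is.na(reason)
  trials$exclusion_reason <- reason
  attr(trials, "retained") <- mean(!trials$excluded)
  trials
}

#' Chance-performance participant inclusion test
#'
#' Exact two-sided binomial test (null probability 0.5) of the response
#' accuracy at each difficulty level; the participant is kept iff at least
#' one level is significantly *above* chance (p < alpha and accuracy > 0.5).
#' Control trials carry no correctness and are ignored.
#'
#' @param trials one participant's trials, exclusions already applied.
#' @param alpha significance level, default 0.05.
#' @param use_excluded include excluded trials? default FALSE.
#' @return list with `keep` (logical) and `table` (per-level n, n_correct,
#'   accuracy, p). Levels with zero trials are skipped with a warning.
#' @export
include_participant <- function(trials, alpha = 0.05, use_excluded = FALSE) {
  tr <- trials[trials$condition == "gratings" & !is.na(trials$correct), ]
  if (!use_excluded && "excluded" %in% names(tr)) tr <- tr[!tr$excluded, ]
  lev <- as.character(1:7)
  res <- data.frame(level = lev, n = 0L, n_correct = 0L,
                    accuracy = NA_real_, p = NA_real_)
  for (j in seq_along(lev)) {
    k <- tr$correct[tr$level == lev[j]]
    res$n[j] <- length(k)
    if (!length(k)) next
    res$n_correct[j] <- sum(k)
    res$accuracy[j] <- mean(k)
    res$p[j] <- stats::binom.test(sum(k), length(k), p = 0.5)$p.value
  }
  if (any(res$n == 0L)) {
    warning(sprintf("levels with zero trials skipped: %s",
                    paste(res$level[res$n == 0L], collapse = ", ")))
  }
  keep <- any(res$p < alpha & res$accuracy > 0.5, na.rm = TRUE)
  list(keep = keep, table = res)
}

#' Per-participant behavioural summary
#'
#' @param trials one participant's trials with exclusions applied.
#' @return list with `by_level` (n, accuracy, median/mean hold per level and
#'   for control), `hold_sd` (SD of hold duration across all retained
#'   gratings trials: the between-subject variability covariate), and
#'   `retained` (fraction of trials kept).
#' @export
behaviour_summary <- function(trials) {
  stopifnot("excluded" %in% names(trials))
  kept <- trials[!trials$excluded, ]
  lev <- c(as.character(1:7), "control")
  by_level <- do.call(rbind, lapply(lev, function(l) {
    k <- kept[kept$level %in% l, ]
    data.frame(level = l, n = nrow(k),
               accuracy = if (l == "control") NA_real_ else mean(k$correct),
               median_hold = stats::median(k$hold),
               mean_hold = mean(k$hold))
  }))
  g <- kept[kept$condition == "gratings", ]
  list(by_level = by_level,
       hold_sd = if (nrow(g) > 1) stats::sd(g$hold) else NA_real_,
       retained = mean(!trials$excluded))
}
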