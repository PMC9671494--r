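#' ECG signal container
#'
#' @param samples numeric vector of amplitudes (mV); must be finite.
#' @param sampling_rate sampling rate in Hz (> 0; 1000 Hz in typical lab use).
#' @param t0 time of the first sample in ms from recording start.
#' @return list of class `"ecg_signal"` with `samples`, `sampling_rate`, `t0`.
#' @export
ecg_signal <- function(samples, sampling_rate, t0 = 0) {
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1 || sampling_rate <= 0) {
    stop("`sampling_rate` must be a single positive number")
  }
  samples <- as.numeric(samples)
  if (any(!is.finite(samples))) stop("`samples` must be finite")
  structure(list(samples = samples, sampling_rate = sampling_rate, t0 = t0),
            class = "ecg_signal")
}

#' @export
print.ecg_signal <- function(x, ...) {
  cat(sprintf("<ecg_signal> %d samples @ %g Hz (%.1f s), t0 = %g ms\n",
              length(x$samples), x$sampling_rate,
              length(x$samples) / x$sampling_rate, x$t0))
  invisible(x)
}

#' Times (ms) of each sample of an ECG signal
#' @param signal an `ecg_signal`.
#' @return numeric vector of sample times in ms.
#' @export
sample_times <- function(signal) {
  signal$t0 + (seq_along(signal$samples) - 1) * 1000 / signal$sampling_rate
}

#' Zero-phase band-pass filter
#'
#' Frequency-domain (FFT) band-pass with raised-cosine transition bands and
#' reflection padding at both ends. Being applied as a real, symmetric gain in
#' the frequency domain, the filter is zero-phase by construction and
#' preserves signal length. Defaults reproduce the 3-30 Hz band used for
#' R-peak detection.
#'
#' @param signal an `ecg_signal`.
#' @param low lower passband edge (Hz), default 3.
#' @param high upper passband edge (Hz), default 30.
#' @param transition transition widths in Hz, length 2 (below `low`, above
#'   `high`); defaults to `c(min(1, low/2), min(5, high/4))`.
#' @return filtered `ecg_signal` of identical length.
#' @export
ecg_bandpass <- function(signal, low = 3, high = 30, transition = NULL) {
  stopifnot(inherits(signal, "ecg_signal"))
  sr <- signal$sampling_rate
  if (!(low > 0 && high > low && high < sr / 2)) {
    stop("band edges must satisfy 0 < low < high < sampling_rate / 2")
  }
  if (is.null(transition)) transition <- c(min(1, low / 2), min(5, high / 4))
  x <- signal$samples
  n <- length(x)
  if (n < 4) return(signal)
  npad <- min(n - 1L, as.integer(round(sr)))  # up to 1 s of reflection
  xp <- c(x[(npad + 1):2], x, x[(n - 1):(n - npad)])
  nfft <- length(xp)
  f <- (seq_len(nfft) - 1) / nfft * sr
  f <- pmin(f, sr - f)   # fold to [0, Nyquist]
  H <- numeric(nfft)
  tl <- transition[1]; th <- transition[2]
  H[f >= low & f <= high] <- 1
  ramp_lo <- f > (low - tl) & f < low
  H[ramp_lo] <- 0.5 * (1 - cos(pi * (f[ramp_lo] - (low - tl)) / tl))
  ramp_hi <- f > high & f < (high + th)
  H[ramp_hi] <- 0.5 * (1 + cos(pi * (f[ramp_hi] - high) / th))
  y <- Re(stats::fft(stats::fft(xp) * H, inverse = TRUE)) / nfft
  ecg_signal(y[(npad + 1):(npad + n)], sr, signal$t0)
}

#' Detect R-peaks
#'
#' Local-maxima picking with a minimum peak-to-peak distance (550 ms default)
#' and a scale-free prominence threshold of
#' `prominence_frac * quantile(|x|, 0.95)`. Candidates are accepted greedily
#' from the largest down, discarding any maximum closer than `min_distance`
#' to an already accepted one (the behaviour of classic `findpeaks`-style
#' pickers).
#'
#' @param signal an `ecg_signal` (normally band-pass filtered first).
#' @param min_distance minimum peak separation in ms (> 0), default 550.
#' @param prominence_frac fraction of the 95th percentile of `|x|` used as
#'   amplitude threshold, default 0.5.
#' @return numeric vector of R-peak times (ms), at sample resolution,
#'   increasing. A flat signal gives an empty vector with a warning.
#' @export
detect_r_peaks <- function(signal, min_distance = 550, prominence_frac = 0.5) {
  stopifnot(inherits(signal, "ecg_signal"))
  if (!is.numeric(min_distance) || min_distance <= 0) {
    stop("`min_distance` must be > 0")
  }
  x <- signal$samples
  n <- length(x)
  if (n < 3 || diff(range(x)) == 0) {
    warning("flat or too-short signal: no R-peaks detected")
    return(numeric(0))
  }
  thr <- prominence_frac * stats::quantile(abs(x), 0.95, names = FALSE)
  i <- 2:(n - 1)
  cand <- i[x[i] > x[i - 1] & x[i] >= x[i + 1] & x[i] >= thr]
  if (!length(cand)) {
    warning("no peaks above the prominence threshold")
    return(numeric(0))
  }
  min_samp <- min_distance * signal$sampling_rate / 1000
  cand <- cand[order(x[cand], decreasing = TRUE)]
  keep <- integer(0)
  for (k in cand) {
    if (!length(keep) || all(abs(keep - k) >= min_samp)) keep <- c(keep, k)
  }
  keep <- sort(keep)
  signal$t0 + (keep - 1) * 1000 / signal$sampling_rate
}

#' T-peak and T-wave end delineation (trapezium-area method)
#'
#' Finds the T-peak as the maximum of the signal in a physiologic search
#' window after the QRS complex, then locates the T-wave end as the sample on
#' the descending limb that maximises the area of the trapezium formed by the
#' T-peak point `(x_m, y_m)`, the candidate point `(x_i, y_i)` and a fixed
#' reference abscissa `x_r` beyond the T-wave:
#' `A_i = 0.5 * (y_m - y_i) * (2 * x_r - x_i - x_m)`.
#' The reference point is `x_r = t_peak + 2 * (t_minslope - t_peak)` capped at
#' `next_r - 50` ms, where `t_minslope` is the point of steepest descent after
#' the T-peak. The returned maximiser equals a brute-force scan over all
#' candidate samples (the implementation *is* an exhaustive vectorised scan).
#'
#' @param signal an `ecg_signal` (use a gentle band, e.g. 0.5-40 Hz; a 3 Hz
#'   high-pass distorts the low-frequency T morphology).
#' @param r_time R-peak time (ms) opening the cycle.
#' @param next_r next R-peak time (ms); the cycle must exceed 400 ms.
#' @param search search window for the T-peak relative to R, in ms:
#'   `[R + search[1], R + min(search[2], search_frac * IBI)]`.
#' @param search_frac fraction of the IBI capping the search window.
#' @param ref_cap the reference abscissa is capped at `next_r - ref_cap` ms.
#' @return list with `t_peak`, `t_end` (ms, `NA` on failure) and `qc`
#'   (`NA` on success, else a failure reason).
#' @export
detect_t_end <- function(signal, r_time, next_r,
                         search = c(150, 500), search_frac = 0.6,
                         ref_cap = 50) {
  stopifnot(inherits(signal, "ecg_signal"))
  fail <- function(why) list(t_peak = NA_real_, t_end = NA_real_, qc = why)
  if (next_r - r_time <= 400) return(fail("cycle shorter than 400 ms"))
  tt <- sample_times(signal)
  dt <- 1000 / signal$sampling_rate
  win <- which(tt >= r_time + search[1] &
                 tt <= r_time + min(search[2], search_frac * (next_r - r_time)))
  if (length(win) < 3) return(fail("T search window empty"))
  x <- signal$samples
  i_peak <- win[which.max(x[win])]
  t_peak <- tt[i_peak]

  # end of the steep descending limb after the T-peak: the last sample whose
  # downward slope is at least half the steepest one (equivalent to the
  # minimum-slope point on rounded T-waves, but well defined when the
  # descent is linear and the slope is constant)
  lim <- which(tt > t_peak & tt <= min(t_peak + 400, next_r - ref_cap))
  if (length(lim) < 2) return(fail("no descending limb found"))
  slopes <- diff(x[c(i_peak, lim)]) / dt
  if (min(slopes) >= 0) return(fail("no descending limb found"))
  i_ms <- lim[max(which(slopes <= 0.5 * min(slopes)))]
  x_r <- min(t_peak + 2 * (tt[i_ms] - t_peak), next_r - ref_cap)

  cand <- which(tt > t_peak & tt < x_r)
  if (length(cand) < 2) return(fail("no descending limb found"))
  y_m <- x[i_peak]
  area <- 0.5 * (y_m - x[cand]) * (2 * x_r - tt[cand] - t_peak)
  i_end <- cand[which.max(area)]
  list(t_peak = t_peak, t_end = tt[i_end], qc = NA_character_)
}

#' Full beat-level event detection on a raw ECG trace
#'
#' Band-pass filters the trace (3-30 Hz) for R-peak detection, delineates the
#' T-peak / T-end of every complete cycle on a gently filtered copy
#' (0.5-40 Hz), assembles the beats and applies the R-T consistency filter.
#'
#' @param signal raw `ecg_signal`.
#' @param band_r filter band for R-peak detection (Hz), default `c(3, 30)`.
#' @param band_t filter band for T-wave delineation (Hz), default `c(0.5, 40)`.
#' @param min_distance minimum R-peak separation (ms), default 550.
#' @param rt_factor consistency-filter multiplier, default 1.5; `NULL` skips
#'   the filter.
#' @param ... further arguments passed to [detect_t_end()].
#' @return `beat_series` with one row per detected R-peak; the last row has no
#'   closing R-peak, so its T-end is undefined and it is QC-flagged.
#' @export
detect_ecg_events <- function(signal, band_r = c(3, 30), band_t = c(0.5, 40),
                              min_distance = 550, rt_factor = 1.5, ...) {
  fil_r <- ecg_bandpass(signal, band_r[1], band_r[2])
  r <- detect_r_peaks(fil_r, min_distance = min_distance)
  if (length(r) < 2) stop("fewer than 2 R-peaks detected")
  fil_t <- ecg_bandpass(signal, band_t[1], band_t[2])
  n <- length(r)
  t_peak <- t_end <- rep(NA_real_, n)
  reason <- c(rep(NA_character_, n - 1L), "no closing R-peak")
  for (i in seq_len(n - 1L)) {
    d <- detect_t_end(fil_t, r[i], r[i + 1], ...)
    t_peak[i] <- d$t_peak
    t_end[i] <- d$t_end
    reason[i] <- d$qc
  }
  beats <- assemble_beats(r, t_end, t_peaks = t_peak, qc_reason = reason)
  if (!is.null(rt_factor)) beats <- rt_consistency_filter(beats, rt_factor)
  beats
}
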