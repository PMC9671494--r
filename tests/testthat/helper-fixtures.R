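# Shared fixture builders. Everything is generated in code at test time;
# nothing here touches the network or large files.

# small synthetic world used by several suites
small_config <- function(seed = 99L, ...) {
  synth_config(n_participants = 6, trials_gratings = 42, trials_control = 14,
               seed = seed, ...)
}

# hand-built trace: baseline, half-cosine rise to a T-like peak, then a
# *linear* descent hitting baseline exactly at sample `k_end`, flat after.
# Geometry predicts the trapezium-area maximiser at the descent breakpoint.
triangular_t_trace <- function(r_time = 0, t_peak = 220, t_end = 340,
                               total = 900, sr = 1000, amp = 0.3) {
  n <- total
  tt <- seq_len(n) - 1
  x <- numeric(n)
  x[tt == r_time] <- 1  # token R spike so the search window anchor is real
  rise <- tt >= (t_peak - 100) & tt <= t_peak
  x[rise] <- amp * 0.5 * (1 - cos(pi * (tt[rise] - (t_peak - 100)) / 100))
  desc <- tt > t_peak & tt <= t_end
  x[desc] <- amp * (t_end - tt[desc]) / (t_end - t_peak)
  ecg_signal(x, sr)
}

# independent brute-force re-implementation of the trapezium maximiser:
# plain loops, no shared code with detect_t_end() beyond the documented
# geometry (T-peak = max in window, reference = end of steep descent rule).
brute_force_t_end <- function(signal, r_time, next_r,
                              search = c(150, 500), search_frac = 0.6,
                              ref_cap = 50) {
  tt <- sample_times(signal)
  x <- signal$samples
  dt <- 1000 / signal$sampling_rate
  win <- which(tt >= r_time + search[1] &
                 tt <= r_time + min(search[2], search_frac * (next_r - r_time)))
  i_peak <- win[which.max(x[win])]
  t_peak <- tt[i_peak]
  lim <- which(tt > t_peak & tt <= min(t_peak + 400, next_r - ref_cap))
  slopes <- numeric(length(lim))
  prev <- i_peak
  for (j in seq_along(lim)) {
    slopes[j] <- (x[lim[j]] - x[prev]) / dt
    prev <- lim[j]
  }
  if (min(slopes) >= 0) return(NA_real_)
  i_ms <- 0
  for (j in seq_along(lim)) if (slopes[j] <= 0.5 * min(slopes)) i_ms <- j
  x_r <- min(t_peak + 2 * (tt[lim[i_ms]] - t_peak), next_r - ref_cap)
  best <- -Inf; best_t <- NA_real_
  for (i in which(tt > t_peak & tt < x_r)) {
    a <- 0.5 * (x[i_peak] - x[i]) * (2 * x_r - tt[i] - t_peak)
    if (a > best) { best <- a; best_t <- tt[i] }
  }
  best_t
}

# align detected beat times to ground truth by nearest R
align_beats <- function(detected, truth) {
  vapply(detected, function(t) which.min(abs(truth - t)), integer(1))
}

# minimal annotated-trial table builder for analysis-level unit tests
fake_phased_trials <- function(participant, onset_window, hold,
                               correct = NA, condition = "gratings",
                               level = "1", offset_window = onset_window,
                               onset_angle = NA_real_,
                               offset_angle = NA_real_,
                               hold_angle = NA_real_) {
  data.frame(participant = participant, condition = condition, level = level,
             onset = seq_along(hold) * 4000, offset = seq_along(hold) * 4000 + hold,
             hold = hold, correct = correct, excluded = FALSE,
             exclusion_reason = NA_character_,
             onset_angle = onset_angle, onset_window = onset_window,
             offset_angle = offset_angle, offset_window = offset_window,
             hold_angle = hold_angle, hold_resultant = NA_real_,
             stringsAsFactors = FALSE)
}
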