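#' Configuration for the synthetic ECG + touch generator
#'
#' Defaults reproduce the descriptive statistics of a typical grating-touch
#' experiment: mean interbeat interval 793 ms with SD 110 ms, electrical
#' systole 342 ms (between-participant SD 23.4 ms), hold durations around
#' 1.1 s clipped into (100, 5000) ms, 12 blocks of 14 trials of which the
#' last two are a flat-stimulus movement control (140 gratings + 28 control
#' trials), and mean accuracy near 83% falling off over the seven difficulty
#' levels. The coupling knobs (`onset_phase_kappa`, `hold_systole_delta`,
#' `ibi_deceleration`) default to 0, i.e. a fully uncoupled null world;
#' analyses inject known effects by raising them.
#'
#' @param n_participants number of simulated participants.
#' @param trials_gratings gratings trials per participant (spread over the 7
#'   difficulty levels in randomised order).
#' @param trials_control control (flat stimulus) trials per participant,
#'   appended after the gratings trials.
#' @param mean_ibi,ibi_sd within-participant interbeat-interval mean and SD
#'   (ms). Gaps are truncated-normal, bounded below by `2 * systole_len`.
#' @param ibi_between_sd between-participant SD of the mean IBI (ms).
#' @param ar1 optional AR(1) coefficient for successive IBIs (0 = none).
#' @param systole_len R-peak to T-wave-end interval (ms).
#' @param systole_between_sd between-participant SD of the systole length.
#' @param systole_scaling `"fixed"` (default; near-constant electrical
#'   systole) or `"bazett"` (scales with the square root of the IBI).
#' @param onset_phase_mu,onset_phase_kappa von Mises mean direction (degrees)
#'   and concentration of touch-onset phases within the cardiac cycle
#'   (kappa = 0 gives uniform onsets).
#' @param hold_base named numeric vector of baseline hold durations (ms) for
#'   difficulty levels `"1"`..`"7"` and `"control"`; must lie inside
#'   `hold_bounds`.
#' @param hold_sd within-participant trial-to-trial hold SD (ms).
#' @param hold_sd_spread participant hold SDs are drawn uniformly from
#'   `hold_sd * (1 +/- hold_sd_spread)`, giving the between-subject touch
#'   variability that the covariate analysis targets.
#' @param hold_systole_delta ms added to holds initiated during systole.
#' @param hold_bounds hard clip bounds (open interval) for hold durations.
#' @param accuracy_by_level probability of a correct response at levels 1-7.
#' @param ibi_deceleration ms added to the diastole of the beat containing
#'   each touch onset (shifts all later beats).
#' @param intertrial_gap uniform bounds (ms) of the gap between a touch
#'   offset and the next trial's earliest onset.
#' @param seed integer root RNG seed. Per-participant child seeds are drawn
#'   from the root stream, in participant order, before any other draws
#'   (documented spawn order; identical seeds give bit-identical datasets).
#' @return validated list of class `"synth_config"`.
#' @export
synth_config <- function(n_participants = 46L,
                         trials_gratings = 140L,
                         trials_control = 28L,
                         mean_ibi = 793, ibi_sd = 110, ibi_between_sd = 60,
                         ar1 = 0,
                         systole_len = 342, systole_between_sd = 23.4,
                         systole_scaling = c("fixed", "bazett"),
                         onset_phase_mu = 0, onset_phase_kappa = 0,
                         hold_base = c("1" = 975, "2" = 975, "3" = 975,
                                       "4" = 975, "5" = 1250, "6" = 1280,
                                       "7" = 1300, control = 700),
                         hold_sd = 430, hold_sd_spread = 0.5,
                         hold_systole_delta = 0,
                         hold_bounds = c(100, 5000),
                         accuracy_by_level = c(0.97, 0.95, 0.93, 0.92,
                                               0.78, 0.68, 0.57),
                         ibi_deceleration = 0,
                         intertrial_gap = c(2000, 3500),
                         seed = 1L) {
  systole_scaling <- match.arg(systole_scaling)
  bad <- function(field, why) {
    stop(sprintf("invalid synth_config: field `%s` %s", field, why),
         call. = FALSE)
  }
  if (n_participants < 1) bad("n_participants", "must be >= 1")
  if (!(mean_ibi > systole_len && systole_len > 0)) {
    bad("mean_ibi/systole_len", "must satisfy mean_ibi > systole_len > 0")
  }
  if (ibi_sd < 0) bad("ibi_sd", "must be >= 0")
  if (onset_phase_kappa < 0) bad("onset_phase_kappa", "must be >= 0")
  if (abs(ar1) >= 1) bad("ar1", "must lie in (-1, 1)")
  if (length(accuracy_by_level) != 7 ||
      any(accuracy_by_level < 0 | accuracy_by_level > 1)) {
    bad("accuracy_by_level", "must be 7 probabilities in [0, 1]")
  }
  need <- c(as.character(1:7), "control")
  if (!all(need %in% names(hold_base))) {
    bad("hold_base", "must be named with levels \"1\"..\"7\" and \"control\"")
  }
  if (any(hold_base <= hold_bounds[1] | hold_base >= hold_bounds[2])) {
    bad("hold_base", sprintf("must lie strictly inside (%g, %g)",
                             hold_bounds[1], hold_bounds[2]))
  }
  if (hold_sd < 0) bad("hold_sd", "must be >= 0")
  if (hold_sd_spread < 0 || hold_sd_spread >= 1) {
    bad("hold_sd_spread", "must lie in [0, 1)")
  }
  if (intertrial_gap[1] <= 0 || intertrial_gap[2] < intertrial_gap[1]) {
    bad("intertrial_gap", "must be increasing positive bounds")
  }
  structure(list(n_participants = as.integer(n_participants),
                 trials_gratings = as.integer(trials_gratings),
                 trials_control = as.integer(trials_control),
                 mean_ibi = mean_ibi, ibi_sd = ibi_sd,
                 ibi_between_sd = ibi_between_sd, ar1 = ar1,
                 systole_len = systole_len,
                 systole_between_sd = systole_between_sd,
                 systole_scaling = systole_scaling,
                 onset_phase_mu = onset_phase_mu,
                 onset_phase_kappa = onset_phase_kappa,
                 hold_base = hold_base, hold_sd = hold_sd,
                 hold_sd_spread = hold_sd_spread,
                 hold_systole_delta = hold_systole_delta,
                 hold_bounds = hold_bounds,
                 accuracy_by_level = accuracy_by_level,
                 ibi_deceleration = ibi_deceleration,
                 intertrial_gap = intertrial_gap,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' von Mises random angles (degrees)
#'
#' Best-Fisher rejection sampler; `kappa = 0` falls back to uniform draws.
#' Used for touch-onset phases.
#'
#' @param n number of draws.
#' @param mu mean direction in degrees.
#' @param kappa concentration (>= 0).
#' @return angles in `[0, 360)`.
#' @export
rvonmises <- function(n, mu = 0, kappa = 0) {
  if (kappa < 0) stop("`kappa` must be >= 0")
  if (kappa < 1e-10) return(stats::runif(n, 0, 360))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    z <- cos(pi * stats::runif(1))
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- stats::runif(1)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      theta <- sign(stats::runif(1) - 0.5) * acos(f)
      out[i] <- (mu + theta * 180 / pi) %% 360
      i <- i + 1L
    }
  }
  out
}

# truncated-normal draws with lower bound (inverse-CDF; deterministic per
# seed). With match_mean = TRUE the underlying location is shifted so the
# *truncated* mean equals `mean` — otherwise a binding bound (e.g. IBIs
# bounded at 2 x systole with mean 793, SD 110) would inflate the sample
# mean above the stated descriptive value.
rtnorm_lower <- function(n, mean, sd, lo, match_mean = FALSE) {
  if (sd <= 0) return(rep(max(mean, lo), n))
  mu <- mean
  if (match_mean && stats::pnorm(lo, mean, sd) > 1e-6) {
    tmean <- function(m) {
      a <- (lo - m) / sd
      m + sd * stats::dnorm(a) / (1 - stats::pnorm(a))
    }
    # when the bound sits at/above the requested mean the target is
    # unreachable; keep the unadjusted location (mean inflates, inevitably)
    mu <- tryCatch(
      stats::uniroot(function(m) tmean(m) - mean,
                     c(mean - 6 * sd, mean + sd), tol = 1e-8)$root,
      error = function(e) mean)
  }
  plo <- stats::pnorm(lo, mu, sd)
  if (plo > 1 - 1e-10) {
    stop(sprintf("truncation bound %g excludes N(%g, %g)", lo, mean, sd))
  }
  stats::qnorm(stats::runif(n, plo, 1), mu, sd)
}

#' Generate a heartbeat train
#'
#' Successive R-peak gaps are (optionally AR(1)-correlated) truncated-normal
#' draws with mean `mean_ibi` and SD `ibi_sd`, bounded below by
#' `2 * systole_len`. Each beat carries a T-end at `R + systole length`,
#' fixed by default or Bazett-like (proportional to the square root of the
#' IBI) when `systole_scaling = "bazett"`.
#'
#' @param config a `synth_config` (only the IBI/systole fields are used).
#' @param duration recording length in ms; must exceed `2 * mean_ibi`.
#'   R-peaks start at 0 and stop strictly before `duration`.
#' @param mean_ibi,systole_len optional participant-level overrides.
#' @return `beat_series`.
#' @export
generate_beat_train <- function(config, duration,
                                mean_ibi = config$mean_ibi,
                                systole_len = config$systole_len) {
  stopifnot(inherits(config, "synth_config"))
  if (duration <= 2 * mean_ibi) stop("`duration` must exceed 2 * mean_ibi")
  lo <- 2 * systole_len
  n_guess <- ceiling(duration / max(mean_ibi - 4 * config$ibi_sd, lo)) + 4L
  gaps <- rtnorm_lower(n_guess, mean_ibi, config$ibi_sd, lo, match_mean = TRUE)
  if (config$ar1 != 0) {
    # AR(1) around the mean; innovations rescaled to keep marginal SD, then
    # re-truncated from below
    e <- gaps - mean_ibi
    a <- config$ar1
    for (i in 2:length(e)) e[i] <- a * e[i - 1] + sqrt(1 - a^2) * e[i]
    gaps <- pmax(mean_ibi + e, lo)
  }
  r <- cumsum(c(0, gaps))
  r <- r[r < duration]
  ibi <- c(diff(r), mean_ibi)
  sys <- switch(config$systole_scaling,
                fixed = rep(systole_len, length(r)),
                bazett = systole_len * sqrt(ibi / mean_ibi))
  beat_series(r, r + sys)
}

#' Generate a touch-event stream over a beat train
#'
#' Touch onsets are placed in successive cardiac cycles with phases drawn
#' from a von Mises distribution (`kappa = 0` = uniform). Hold duration is
#' `hold_base[level] + hold_systole_delta * [onset in systole] + noise`,
#' clipped just inside `hold_bounds`. Response correctness is Bernoulli with
#' the level's accuracy (NA for control trials). If `ibi_deceleration > 0`
#' the cycle containing each onset is lengthened by that amount and all later
#' beats are shifted, i.e. the deceleration is carried entirely by the
#' diastole of the onset beat. Inter-trial gaps guarantee non-overlap.
#'
#' Ground-truth columns (`true_systole`, `true_phase`, `cycle`) are stored so
#' that tests never need to re-derive truth from the pipeline under test.
#'
#' @param config a `synth_config`.
#' @param beats a `beat_series` from [generate_beat_train()]; must be long
#'   enough for the requested trial count.
#' @param hold_sd participant-level override of the hold SD.
#' @param start_time earliest allowed onset (ms); leave a few cycles of
#'   context before the first trial.
#' @return list with `trials` (data.frame: condition, level, onset, offset,
#'   hold, correct, cycle, true_phase, true_systole) and `beats` (the beat
#'   series with any onset-locked decelerations applied).
#' @export
generate_touch_stream <- function(config, beats, hold_sd = config$hold_sd,
                                  start_time = 5 * config$mean_ibi) {
  stopifnot(inherits(config, "synth_config"), inherits(beats, "beat_series"))
  if (nrow(beats) < 10) stop("`beats` must contain at least 10 beats")
  n_g <- config$trials_gratings
  n_c <- config$trials_control
  levels_g <- rep_len(as.character(1:7), n_g)
  if (n_g > 0) levels_g <- sample(levels_g)
  level <- c(levels_g, rep("control", n_c))
  n_trials <- length(level)

  r <- beats$r_time
  t_end <- beats$t_end
  nb <- length(r)
  onset <- offset <- hold <- true_phase <- numeric(n_trials)
  cycle <- integer(n_trials)
  in_sys <- logical(n_trials)
  correct <- rep(NA, n_trials)

  gaps <- stats::runif(n_trials, config$intertrial_gap[1], config$intertrial_gap[2])
  theta <- rvonmises(n_trials, config$onset_phase_mu, config$onset_phase_kappa)
  noise <- stats::rnorm(n_trials, 0, hold_sd)
  u_corr <- stats::runif(n_trials)

  cursor <- start_time
  for (k in seq_len(n_trials)) {
    target <- cursor + gaps[k]
    i <- which(r >= target)[1]
    if (is.na(i) || i >= nb) {
      stop(sprintf("beat train exhausted at trial %d of %d; supply a longer train",
                   k, n_trials))
    }
    ibi_i <- r[i + 1] - r[i]
    onset[k] <- r[i] + theta[k] / 360 * ibi_i
    in_sys[k] <- onset[k] < t_end[i]
    base <- config$hold_base[[level[k]]]
    h <- base + config$hold_systole_delta * in_sys[k] + noise[k]
    h <- min(max(h, config$hold_bounds[1] + 1), config$hold_bounds[2] - 1)
    hold[k] <- h
    offset[k] <- onset[k] + h
    if (level[k] != "control") {
      correct[k] <- u_corr[k] < config$accuracy_by_level[as.integer(level[k])]
    }
    if (config$ibi_deceleration > 0) {
      idx <- (i + 1):nb
      r[idx] <- r[idx] + config$ibi_deceleration
      t_end[idx] <- t_end[idx] + config$ibi_deceleration
    }
    cycle[k] <- i
    true_phase[k] <- (onset[k] - r[i]) / (r[i + 1] - r[i]) * 360
    cursor <- offset[k]
  }
  out_beats <- beat_series(r, t_end)
  trials <- data.frame(condition = ifelse(level == "control", "control", "gratings"),
                       level = level, onset = onset, offset = offset,
                       hold = hold, correct = as.logical(correct),
                       cycle = cycle, true_phase = true_phase,
                       true_systole = in_sys,
                       stringsAsFactors = FALSE)
  list(trials = trials, beats = out_beats)
}

#' Simulate one participant
#'
#' Draws participant-level parameters (mean IBI, systole length, hold SD)
#' from their between-participant distributions, generates a beat train long
#' enough for the trial schedule and overlays the touch stream.
#'
#' @param config a `synth_config`.
#' @param id participant identifier (character).
#' @param seed participant child seed (integer).
#' @return list with `id`, `beats`, `trials` (with `participant` column) and
#'   the drawn `params`.
#' @export
simulate_participant <- function(config, id, seed) {
  set.seed(seed)
  mean_ibi_p <- rtnorm_lower(1, config$mean_ibi, config$ibi_between_sd,
                             2.2 * config$systole_len, match_mean = TRUE)
  sys_p <- rtnorm_lower(1, config$systole_len, config$systole_between_sd, 150)
  hold_sd_p <- config$hold_sd *
    stats::runif(1, 1 - config$hold_sd_spread, 1 + config$hold_sd_spread)
  n_trials <- config$trials_gratings + config$trials_control
  per_trial <- config$intertrial_gap[2] + max(config$hold_base) + 4 * config$hold_sd
  duration <- 10 * mean_ibi_p + n_trials * per_trial +
    n_trials * config$ibi_deceleration
  beats <- generate_beat_train(config, duration, mean_ibi = mean_ibi_p,
                               systole_len = sys_p)
  st <- generate_touch_stream(config, beats, hold_sd = hold_sd_p)
  st$trials <- cbind(participant = id, st$trials, stringsAsFactors = FALSE)
  list(id = id, beats = st$beats, trials = st$trials,
       params = list(mean_ibi = mean_ibi_p, systole_len = sys_p,
                     hold_sd = hold_sd_p))
}

#' Simulate a full multi-participant dataset
#'
#' One root seed; per-participant child seeds are drawn first, in participant
#' order, so the dataset is bit-identical for identical configurations.
#'
#' @param config a `synth_config`.
#' @return object of class `"touch_dataset"`: list with `trials` (stacked
#'   data.frame), `beats` (named list of `beat_series`), `params` (named list)
#'   and `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, config$n_participants)
  ids <- sprintf("P%02d", seq_len(config$n_participants))
  sims <- Map(function(id, s) simulate_participant(config, id, s), ids, seeds)
  trials <- do.call(rbind, lapply(sims, `[[`, "trials"))
  rownames(trials) <- NULL
  structure(list(trials = trials,
                 beats = stats::setNames(lapply(sims, `[[`, "beats"), ids),
                 params = stats::setNames(lapply(sims, `[[`, "params"), ids),
                 config = config),
            class = "touch_dataset")
}

#' @export
print.touch_dataset <- function(x, ...) {
  cat(sprintf("<touch_dataset> %d participants, %d trials, %d beat series\n",
              length(x$beats), nrow(x$trials), length(x$beats)))
  invisible(x)
}

#' Render a synthetic ECG waveform from a beat train
#'
#' Places a template PQRST complex at every beat: a small P wave, a sharp
#' triangular R spike (apex exactly at the R time) flanked by Q/S dips, and a
#' T wave that rises as a half-cosine to the T-peak and then descends
#' *linearly* to baseline exactly at the beat's T-end (so the trapezium-area
#' delineator has a geometrically known ground truth). Optional white noise.
#'
#' @param beats a `beat_series` (may be empty).
#' @param sampling_rate Hz, >= 250 (default 1000).
#' @param duration waveform length in ms; defaults to the last R + 1000.
#' @param noise_sd additive Gaussian noise SD (signal units; R apex = 1).
#' @param t_amp T-wave peak amplitude, default 0.3.
#' @return `ecg_signal`.
#' @export
render_ecg <- function(beats, sampling_rate = 1000, duration = NULL,
                       noise_sd = 0, t_amp = 0.3) {
  if (sampling_rate < 250) stop("`sampling_rate` must be >= 250 Hz")
  if (is.null(duration)) {
    duration <- if (nrow(beats)) max(beats$r_time) + 1000 else 0
  }
  n <- as.integer(ceiling(duration * sampling_rate / 1000))
  x <- numeric(n)
  tt <- (seq_len(n) - 1) * 1000 / sampling_rate
  add_window <- function(lo, hi, f) {
    i1 <- max(1L, as.integer(floor(lo * sampling_rate / 1000)) + 1L)
    i2 <- min(n, as.integer(ceiling(hi * sampling_rate / 1000)) + 1L)
    if (i1 > i2) return(invisible())
    idx <- i1:i2
    x[idx] <<- x[idx] + f(tt[idx])
  }
  for (b in seq_len(nrow(beats))) {
    r <- beats$r_time[b]
    te <- beats$t_end[b]
    tp <- beats$t_peak[b]
    if (is.na(tp)) tp <- r + 0.62 * (te - r)
    # P wave
    add_window(r - 220, r - 100,
               function(t) 0.12 * exp(-0.5 * ((t - (r - 160)) / 20)^2))
    # Q and S dips
    add_window(r - 55, r - 5,
               function(t) -0.15 * exp(-0.5 * ((t - (r - 30)) / 8)^2))
    add_window(r + 5, r + 55,
               function(t) -0.2 * exp(-0.5 * ((t - (r + 30)) / 8)^2))
    # R spike: triangle, apex at r
    add_window(r - 25, r + 25,
               function(t) pmax(0, 1 - abs(t - r) / 25))
    if (!is.na(te)) {
      rise <- tp - 110
      add_window(rise, te, function(t) {
        ifelse(t <= tp,
               t_amp * 0.5 * (1 - cos(pi * (t - rise) / (tp - rise))),
               t_amp * pmax(0, (te - t) / (te - tp)))
      })
    }
  }
  if (noise_sd > 0) x <- x + stats::rnorm(n, 0, noise_sd)
  ecg_signal(x, sampling_rate)
}
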