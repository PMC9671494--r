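test_that("phase proportions renormalise over assigned events", {
  tr <- fake_phased_trials("P1",
                          onset_window = rep(c("systole", "diastole"),
                                             c(48, 52)),
                          hold = rep(1000, 100))
  pp <- phase_proportions(tr)
  expect_equal(pp$table$prop_start_systole, 0.48)
  expect_equal(pp$table$prop_end_systole, 0.48)

  all_sys <- fake_phased_trials("P1", rep("systole", 10), rep(1000, 10))
  expect_equal(phase_proportions(all_sys)$table$prop_start_systole, 1)

  # cells under min_trials give NA
  few <- fake_phased_trials("P1", rep("systole", 3), rep(1000, 3))
  expect_true(is.na(phase_proportions(few, min_trials = 5)$table$prop_start_systole))

  # uniform synthetic onsets: group mean near chance
  ds <- simulate_dataset(small_config(seed = 3L))
  ph <- annotate_phases(apply_exclusions(ds$trials, beats = ds$beats),
                        ds$beats, events = c("onset", "offset"))
  tab <- phase_proportions(ph)$table
  g <- tab[tab$condition == "gratings", ]
  expect_lt(abs(mean(g$prop_start_systole) - 0.5), 0.08)

  # oracle: naive single-pass recomputation per participant
  for (i in seq_len(nrow(g))) {
    d <- ph[ph$participant == g$participant[i] & ph$condition == "gratings" &
              !ph$excluded, ]
    ns <- 0; nd <- 0
    for (w in d$onset_window) {
      if (identical(w, "systole")) ns <- ns + 1
      if (identical(w, "diastole")) nd <- nd + 1
    }
    expect_equal(g$prop_start_systole[i], ns / (ns + nd))
  }
})

test_that("duration by initiation phase: degenerate and null cases", {
  # single participant, equal holds: difference 0
  tr <- fake_phased_trials("P1",
                          onset_window = rep(c("systole", "diastole"), 10),
                          hold = rep(1000, 20))
  d <- duration_by_initiation_phase(tr)
  expect_equal(d$per_participant$mean_hold, c(1000, 1000))
  expect_null(d$contrasts)  # paired contrast needs >= 3 participants

  # participants missing a cell are dropped from the contrast
  set.seed(88)
  tr2 <- rbind(tr,
               fake_phased_trials("P2", rep(c("systole", "diastole"), 10),
                                  rnorm(20, 1000, 10)),
               fake_phased_trials("P3", rep(c("systole", "diastole"), 10),
                                  rnorm(20, 1000, 10)),
               fake_phased_trials("P4", rep("systole", 10), rep(900, 10)))
  ct <- duration_by_initiation_phase(tr2)$contrasts
  expect_equal(ct$n, 3)
  # null world: CI straddles zero
  expect_lt(ct$ci_lo, 0)
  expect_gt(ct$ci_hi, 0)
})

test_that("accuracy by phase recovers planted phase-dependent accuracy", {
  mk <- function(id) {
    win <- rep(c("systole", "diastole"), each = 40)
    correct <- c(rep(c(TRUE, FALSE), c(36, 4)),   # 0.9 in systole
                 rep(c(TRUE, FALSE), c(28, 12)))  # 0.7 in diastole
    fake_phased_trials(id, win, rep(1000, 80), correct = correct)
  }
  acc <- accuracy_by_phase(rbind(mk("P1"), mk("P2")), by_level = FALSE)
  a <- acc[acc$event_type == "start", ]
  gap <- mean(a$accuracy[a$phase == "systole"]) -
    mean(a$accuracy[a$phase == "diastole"])
  expect_equal(gap, 0.2, tolerance = 1e-12)

  all_right <- fake_phased_trials("P1", rep(c("systole", "diastole"), 10),
                                  rep(1000, 20), correct = TRUE)
  acc2 <- accuracy_by_phase(all_right, by_level = FALSE)
  expect_true(all(acc2$accuracy == 1))
})

test_that("variability covariate: Pearson r on constructed data", {
  mk <- function(id, sdev, acc_n) {
    n <- 40
    holds <- 1000 + sdev * rep(c(-1, 1), n / 2)   # sample sd ~ sdev
    correct <- rep(c(TRUE, FALSE), c(acc_n, n - acc_n))
    fake_phased_trials(id, rep(c("systole", "diastole"), n / 2), holds,
                       correct = correct)
  }
  # accuracy strictly increasing with hold SD -> r near 1
  tr <- rbind(mk("P1", 50, 20), mk("P2", 150, 26), mk("P3", 250, 32),
              mk("P4", 350, 38))
  v <- variability_covariate_analysis(tr)
  expect_gt(v$pearson$r, 0.97)
  expect_equal(v$pearson$n, 4)
  expect_equal(v$table$diff_dia_sys,
               -(v$table$mean_hold_sys - v$table$mean_hold_dia))

  # zero-variance covariate is flagged
  tr0 <- rbind(mk("P1", 100, 20), mk("P2", 100, 26), mk("P3", 100, 32))
  v0 <- variability_covariate_analysis(tr0)
  expect_true(is.na(v0$pearson$r))
})

test_that("IBI position analysis: constant IBI and null profiles are flat", {
  b <- beat_series(seq(0, 8000, by = 800), seq(0, 8000, by = 800) + 342)
  tr <- data.frame(participant = "P1", onset = c(2500, 4100), condition = "gratings")
  ctx <- ibi_contexts(tr, list(P1 = b))
  res <- ibi_position_analysis(ctx)
  expect_true(all(res$group$ibi == 800))
  expect_true(all(res$group$systole == 342))
  expect_true(all(res$group$diastole == 458))
  # identically-zero differences get p = 1 by convention
  expect_true(all(res$posthoc$p[res$posthoc$measure == "ibi"] == 1))
})

test_that("group circular summary: point mass, recovery, level correction", {
  # every participant mean at 90 degrees
  tr <- do.call(rbind, lapply(sprintf("P%d", 1:6), function(id) {
    fake_phased_trials(id, rep("systole", 4), rep(1000, 4),
                       onset_angle = 90)
  }))
  g <- group_circular_summary(tr)
  start <- g[g$event_type == "start", ]
  expect_equal(start$mean_deg, 90)
  expect_equal(start$resultant, 1)
  expect_lt(start$p, 0.001)

  # von Mises recovery: group mean within a few degrees of mu
  set.seed(23)
  ds <- simulate_dataset(synth_config(n_participants = 10, trials_gratings = 42,
                                      trials_control = 0, onset_phase_mu = 150,
                                      onset_phase_kappa = 2, seed = 61L))
  ph <- annotate_phases(apply_exclusions(ds$trials), ds$beats,
                        events = "onset")
  gg <- group_circular_summary(ph)
  row <- gg[gg$event_type == "start" & gg$condition == "gratings", ]
  expect_lt(abs(((row$mean_deg - 150 + 180) %% 360) - 180), 20)
  expect_lt(row$p, 0.05)

  # Holm correction applied within the 7-level families only
  ph$level <- rep_len(as.character(1:7), nrow(ph))
  gl <- group_circular_summary(ph, by_level = TRUE)
  lv <- gl[gl$level != "all" & gl$event_type == "start", ]
  expect_equal(nrow(lv), 7L)
  expect_true(all(lv$p_adj >= lv$p, na.rm = TRUE))
  expect_true(all(is.na(gl$p_adj[gl$level == "all"])))
})
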