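amp_map <- c("1" = 1, "2" = 2, "3" = 3, "4" = 4, "5" = 5, "6" = 6, "7" = 7,
             control = 8)

test_that("pulse channel parsing: plateaus, merging, unknown levels", {
  v <- numeric(6000)
  v[1001:2000] <- 3                       # level 3, 1000 ms
  v[2501:2600] <- 5; v[2641:2800] <- 5    # two contacts 40 ms apart
  v[4001:4500] <- 2.5                     # halfway between levels: unknown
  v[5001:5300] <- 8                       # control
  tr <- parse_pulse_channel(ecg_signal(v, 1000), amp_map)
  expect_equal(nrow(tr), 4L)
  expect_equal(tr$level[1], "3")
  expect_equal(tr$hold[1], 1000)
  expect_equal(tr$flag_reason[2], "multiple_contacts")
  expect_equal(tr$n_contacts[2], 2L)
  expect_equal(tr$flag_reason[3], "unknown_level")
  expect_equal(tr$condition[4], "control")

  # runs further apart than merge_gap stay separate trials
  v2 <- numeric(3000); v2[501:800] <- 2; v2[1201:1500] <- 2
  tr2 <- parse_pulse_channel(ecg_signal(v2, 1000), amp_map)
  expect_equal(nrow(tr2), 2L)
  expect_true(all(tr2$n_contacts == 1L))

  expect_equal(nrow(parse_pulse_channel(ecg_signal(numeric(100), 1000),
                                        amp_map)), 0L)
  expect_error(parse_pulse_channel(ecg_signal(v, 1000), c(a = 1, b = 1)),
               "injective")
})

test_that("exclusion rules flag planted violations, and only those", {
  base_holds <- rep(c(900, 1000, 1100), 12)  # sd ~ 83, mean 1000
  holds <- c(base_holds, 99, 5001, 2500)     # short, long, > 3 SD outlier
  n <- length(holds)
  trials <- data.frame(participant = "P1", condition = "gratings",
                       level = rep_len(as.character(1:7), n),
                       onset = cumsum(rep(6000, n)),
                       offset = cumsum(rep(6000, n)) + holds,
                       hold = holds, correct = TRUE,
                       n_contacts = c(rep(1L, n - 1L), 1L))
  trials$n_contacts[3] <- 2L                 # planted multi-contact
  resp <- rep(NA_real_, n)
  resp[5] <- trials$offset[5] - 50           # spoke before releasing
  out <- apply_exclusions(trials, response_times = resp)
  expect_equal(which(out$excluded), c(3L, 5L, n - 2L, n - 1L, n))
  expect_equal(out$exclusion_reason[3], "multiple_contacts")
  expect_equal(out$exclusion_reason[5], "response_before_release")
  expect_equal(out$exclusion_reason[n - 2L], "too_short")
  expect_equal(out$exclusion_reason[n - 1L], "too_long")
  expect_equal(out$exclusion_reason[n], "duration_outlier")
  expect_equal(attr(out, "retained"), (n - 5) / n)
})

test_that("trials overlapping QC-failed beats are excluded", {
  beats <- beat_series(seq(0, 8000, by = 800), seq(0, 8000, by = 800) + 342,
                       qc_reason = c(rep(NA, 5), "rt_inconsistent",
                                     rep(NA, 5)))
  trials <- data.frame(participant = "P1", condition = "gratings",
                       level = "1",
                       onset = c(900, 4100, 6500), hold = c(500, 500, 500),
                       correct = TRUE)
  trials$offset <- trials$onset + trials$hold
  out <- apply_exclusions(trials, beats = beats)
  # beat 6 covers [4000, 4800): trial 2 overlaps it
  expect_equal(out$excluded, c(FALSE, TRUE, FALSE))
  expect_equal(out$exclusion_reason[2], "beat_qc")

  # clean bounded data: retained fraction is exactly 100%
  expect_equal(attr(apply_exclusions(trials[c(1, 3), ], beats = beats),
                    "retained"), 1)
})

test_that("chance-performance inclusion uses the exact binomial test", {
  mk <- function(n_correct, n_per_level = 20) {
    do.call(rbind, lapply(1:7, function(l) {
      data.frame(participant = "P1", condition = "gratings",
                 level = as.character(l),
                 onset = 1, offset = 1001, hold = 1000,
                 correct = rep(c(TRUE, FALSE),
                               c(n_correct[l], n_per_level - n_correct[l])),
                 excluded = FALSE)
    }))
  }
  perfect <- include_participant(mk(c(20, rep(10, 6))))
  expect_true(perfect$keep)
  expect_equal(perfect$table$p[1], 2 * 0.5^20, tolerance = 1e-12)

  chance <- include_participant(mk(rep(10, 7)))
  expect_false(chance$keep)
  expect_true(all(chance$table$p == 1))

  # 15/20: two-sided exact p = 2 * P(X >= 15) = 0.04139
  borderline <- include_participant(mk(c(15, rep(10, 6))))
  expect_true(borderline$keep)
  expect_equal(borderline$table$p[1], 0.041389, tolerance = 1e-4)

  # significantly *below* chance does not qualify
  below <- include_participant(mk(c(2, rep(10, 6))))
  expect_false(below$keep)

  # empty level warns and is skipped
  d <- mk(rep(10, 7)); d <- d[d$level != "7", ]
  expect_warning(include_participant(d), "zero trials")
})

test_that("behaviour summary: medians, accuracy, variability covariate", {
  tr <- data.frame(participant = "P1", condition = "gratings", level = "1",
                   onset = 1:3, offset = 1:3 + c(900, 1000, 1100),
                   hold = c(900, 1000, 1100), correct = c(TRUE, TRUE, FALSE),
                   excluded = FALSE)
  s <- behaviour_summary(tr)
  expect_equal(s$by_level$median_hold[1], 1000)
  expect_equal(s$by_level$accuracy[1], 2 / 3)
  expect_equal(s$retained, 1)

  same <- tr; same$hold <- 1000; same$offset <- same$onset + 1000
  expect_equal(behaviour_summary(same)$hold_sd, 0)

  # generator round-trip: per-level accuracy inside the binomial CI
  ds <- simulate_dataset(small_config(seed = 55L))
  tr2 <- apply_exclusions(ds$trials)
  for (l in c("1", "7")) {
    k <- tr2[!tr2$excluded & tr2$level == l, "correct"]
    ci <- binom.test(sum(k), length(k))$conf.int
    expect_gte(small_config()$accuracy_by_level[as.integer(l)], ci[1] - 1e-9)
    expect_lte(small_config()$accuracy_by_level[as.integer(l)], ci[2] + 1e-9)
  }
})
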