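test_that("band-pass filter frequency response matches the oracle", {
  sr <- 1000
  tt <- seq(0, 10, by = 1 / sr)
  amp_ratio <- function(freq) {
    x <- ecg_signal(sin(2 * pi * freq * tt), sr)
    y <- ecg_bandpass(x, 3, 30)
    # discard edges where padding transients live
    core <- seq(2 * sr, length(tt) - 2 * sr)
    sd(y$samples[core]) / sd(x$samples[core])
  }
  expect_lt(amp_ratio(1), 0.10)
  expect_gt(amp_ratio(10), 0.90)

  dc <- ecg_bandpass(ecg_signal(rep(2, 4000), sr), 3, 30)
  expect_lt(max(abs(dc$samples)), 1e-6)

  expect_error(ecg_bandpass(ecg_signal(rnorm(100), 100), 3, 60), "Nyquist|band")
  expect_error(ecg_bandpass(ecg_signal(rnorm(100), 1000), 30, 3), "band")
})

test_that("R-peak detection: distance rule, threshold, degenerate inputs", {
  sr <- 1000
  tri <- function(center, amp, tt) amp * pmax(0, 1 - abs(tt - center) / 25)
  tt <- seq(0, 2000)
  x <- tri(500, 1, tt) + tri(800, 0.8, tt)  # 300 ms apart
  pk <- detect_r_peaks(ecg_signal(x, sr), min_distance = 550)
  expect_equal(pk, 500)  # only the larger survives

  expect_warning(pk0 <- detect_r_peaks(ecg_signal(rep(0, 1000), sr)), "flat")
  expect_length(pk0, 0)

  # signal shorter than min_distance: at most one peak
  short <- ecg_signal(tri(200, 1, seq(0, 400)), sr)
  expect_lte(length(detect_r_peaks(short, 550)), 1L)
})

test_that("detector round-trip on noise-free synthetic ECG", {
  set.seed(21)
  cfg <- synth_config()
  raw <- generate_beat_train(cfg, 25000)
  truth <- beat_series(raw$r_time + 500, raw$t_end + 500)  # keep 1st complex whole
  sig <- render_ecg(truth, 1000)
  det <- detect_ecg_events(sig)
  idx <- align_beats(det$r_time, truth$r_time)
  expect_equal(length(unique(idx)), nrow(det))  # one-to-one
  expect_true(all(abs(det$r_time - truth$r_time[idx]) <= 1))
  interior <- seq_len(nrow(det) - 1L)           # last beat has no closing R
  expect_true(all(det$qc_pass[interior]))
  expect_true(all(abs(det$t_end[interior] - truth$t_end[idx][interior]) <= 10))
})

test_that("T-end equals brute-force trapezium maximisation and geometry", {
  # triangular descent hitting baseline at a known sample
  sig <- triangular_t_trace(r_time = 0, t_peak = 220, t_end = 340)
  d <- detect_t_end(sig, 0, 900)
  expect_true(is.na(d$qc))
  expect_equal(d$t_peak, 220)
  expect_lt(abs(d$t_end - 340), 1.5)
  expect_equal(d$t_end, brute_force_t_end(sig, 0, 900))

  # brute-force equivalence across noisy synthetic traces (delineated on
  # the gently filtered signal, as the pipeline does)
  set.seed(33)
  for (rep in 1:8) {
    te_true <- sample(300:380, 1)
    sig2 <- triangular_t_trace(t_peak = sample(180:240, 1), t_end = te_true)
    sig2$samples <- sig2$samples + rnorm(length(sig2$samples), 0, 0.005)
    sig2 <- ecg_bandpass(sig2, 0.5, 40)
    d2 <- detect_t_end(sig2, 0, 900)
    expect_equal(d2$t_end, brute_force_t_end(sig2, 0, 900))
    expect_lt(abs(d2$t_end - te_true), 15)
  }

  # error paths: no descent after the QRS; too-short cycle
  tt <- seq(0, 899)
  rising <- ecg_signal(pmin(1, tt / 800), 1000)
  expect_match(detect_t_end(rising, 0, 900)$qc, "descending")
  expect_match(detect_t_end(sig, 0, 350)$qc, "short")
})

test_that("T-end error degrades monotonically with noise", {
  set.seed(44)
  cfg <- synth_config(ibi_sd = 80)
  raw <- generate_beat_train(cfg, 20000)
  truth <- beat_series(raw$r_time + 500, raw$t_end + 500)
  clean <- render_ecg(truth, 1000)
  rms <- sqrt(mean(clean$samples^2))
  err <- vapply(c(Inf, 30, 20, 10), function(snr) {
    nsd <- if (is.infinite(snr)) 0 else rms / 10^(snr / 20)
    set.seed(45)
    sig <- clean
    if (nsd > 0) sig$samples <- sig$samples + rnorm(length(sig$samples), 0, nsd)
    det <- detect_ecg_events(sig)
    idx <- align_beats(det$r_time, truth$r_time)
    ok <- det$qc_pass
    mean(abs(det$t_end[ok] - truth$t_end[idx][ok]))
  }, numeric(1))
  expect_true(all(diff(err) >= 0))
  expect_lt(err[3], 10)  # <= 10 ms at SNR 20 dB
})

test_that("assemble_beats flags ordering violations and computes IBIs", {
  b <- assemble_beats(c(0, 800, 1600), c(342, 1142, 1942))
  expect_true(all(b$qc_pass))
  expect_equal(b$ibi, c(800, 800, NA))
  expect_equal(attr(b, "median_rt"), 342)

  # t_end after the next R fails that beat only
  b2 <- assemble_beats(c(0, 800, 1600), c(850, 1142, 1942))
  expect_false(b2$qc_pass[1])
  expect_match(b2$qc_reason[1], "ordering")
  expect_true(all(b2$qc_pass[2:3]))

  expect_error(beat_series(c(0, 800, 700), c(342, 1142, 1042)), "increasing")
})

test_that("R-T consistency filter applies the 1.5 x median rule", {
  b <- beat_series(c(0, 800, 1600, 2400, 3200),
                   c(340, 1140, 1942, 2740, 4100))
  # median R-T of passing beats is 342; beat 5 (R-T 900 > 342 + 513) fails
  f <- rt_consistency_filter(b, factor = 1.5)
  expect_equal(f$qc_pass, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(f$qc_reason[5], "rt_inconsistent")

  all_equal <- rt_consistency_filter(beat_series(c(0, 800, 1600, 2400),
                                                 c(342, 1142, 1942, 2742)))
  expect_true(all(all_equal$qc_pass))

  b3 <- beat_series(c(0, 800, 1600), c(700, 1000, 1700))
  expect_error(rt_consistency_filter(b3, factor = 0.1), "rejected")
})
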