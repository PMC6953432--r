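test_that("concatenated Welch spectra localize tones and respect Parseval", {
  fs <- 1000
  t <- seq(1 / fs, 30, by = 1 / fs)
  x <- sin(2 * pi * 20 * t)
  ev <- tibble::tibble(start_s = c(2, 10, 20), stop_s = c(5, 13.5, 24))
  ps <- concatenated_welch(x, fs, ev)
  expect_equal(ps$frequency_hz[which.max(ps$psd)], 20)
  bp <- attr(ps, "band_powers")
  expect_gt(bp[["beta"]] / sum(bp), 0.9)
  # two identical events give the same spectrum as one (averaging invariance)
  x2 <- make_burst_signal(list(), 10, fs, seed = 1)
  one <- concatenated_welch(x2, fs, tibble::tibble(start_s = 2, stop_s = 4))
  idx <- round(2 * fs + 1):round(4 * fs)
  x3 <- x2
  x3[round(6 * fs + 1):round(8 * fs)] <- x2[idx]
  two <- concatenated_welch(
    x3, fs, tibble::tibble(start_s = c(2, 6), stop_s = c(4, 8)))
  expect_equal(two$psd, one$psd, tolerance = 1e-10)
  expect_error(concatenated_welch(x, fs, ev[0, ]), "no oscillatory events")
})

test_that("white-noise total power matches the signal variance", {
  set.seed(10)
  fs <- 1000
  x <- rnorm(120 * fs, sd = 3)
  ev <- tibble::tibble(start_s = seq(1, 111, by = 10),
                       stop_s = seq(1, 111, by = 10) + 8)
  ps <- concatenated_welch(x, fs, ev)
  tot <- sum(ps$psd) * diff(ps$frequency_hz[1:2])
  expect_lt(abs(tot - 9) / 9, 0.1)
})

test_that("band powers integrate left-closed half-open bands", {
  flat <- tibble::tibble(frequency_hz = 0:500, psd = rep(1, 501))
  expect_equal(band_power(flat, "beta"), 18)
  expect_equal(band_power(flat, c(4, 12)) + band_power(flat, c(12, 30)) +
                 band_power(flat, c(30, 100)), band_power(flat, c(4, 100)))
  # a tone exactly at 30 Hz counts as gamma, not beta
  fs <- 1000
  t <- seq(1 / fs, 20, by = 1 / fs)
  ps <- concatenated_welch(sin(2 * pi * 30 * t), fs,
                           tibble::tibble(start_s = 1, stop_s = 19))
  # the tone bin (30 Hz) goes to gamma; beta sees only the Hann leakage
  # into bins 28-29 (mainlobe weight ~1/5 of the gamma share)
  expect_gt(band_power(ps, "gamma"), 4 * band_power(ps, "beta"))
  expect_error(band_power(flat, c(600, 700)), "empty")
})

test_that("modulation index follows its bounded contrast definition", {
  expect_equal(modulation_index(5, 5), 0)
  expect_equal(modulation_index(2, 6), 0.5)
  expect_equal(modulation_index(0, 3), 1)
  expect_true(is.na(modulation_index(0, 0)))
})

test_that("stimulation windows compare pre and during-ramp band power", {
  fs <- 1000
  set.seed(11)
  epoch <- tibble::tibble(ramp_onset_s = 5, ramp_offset_s = 8)
  # stationary noise: MI near 0 on average (each draw compares two short
  # 1.5-s band-power estimates, so single draws scatter by ~0.15)
  mis <- vapply(1:10, function(s) {
    set.seed(s)
    stim_power_pair(rnorm(12 * fs), fs, epoch, "beta")$modulation_index
  }, numeric(1))
  expect_true(all(abs(mis) < 0.5))
  expect_lt(abs(mean(mis)), 0.12)
  # beta tone injected only in the stim window
  x <- rnorm(12 * fs)
  idx <- (6500 * fs / 1000 + 1):(8000 * fs / 1000)
  x[idx] <- x[idx] + 3 * sin(2 * pi * 20 * (idx / fs))
  sp <- stim_power_pair(x, fs, epoch, "beta")
  expect_gt(sp$modulation_index, 0.8)
  expect_lt(abs(stim_power_pair(x, fs, epoch, "theta")$modulation_index), 0.35)
  expect_error(stim_power_pair(rnorm(6 * fs), fs, epoch, "beta"),
               "beyond the recording")
})

test_that("band powers scale as amplitude squared and MI is scale-free", {
  fs <- 1000
  x <- make_burst_signal(list(c(2, 6)), 10, fs, amp = 5, seed = 12)
  ev <- tibble::tibble(start_s = 2, stop_s = 6)
  p1 <- glance(concatenated_welch(x, fs, ev))
  p2 <- glance(concatenated_welch(3 * x, fs, ev))
  expect_equal(p2$beta / p1$beta, 9, tolerance = 1e-6)
  expect_equal(p2$theta / p1$theta, 9, tolerance = 1e-6)
  epoch <- tibble::tibble(ramp_onset_s = 4, ramp_offset_s = 7)
  set.seed(13)
  y <- rnorm(10 * fs)
  expect_equal(stim_power_pair(y, fs, epoch, "beta")$modulation_index,
               stim_power_pair(5 * y, fs, epoch, "beta")$modulation_index)
})
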