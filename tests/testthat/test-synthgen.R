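spec_small <- function(seed = 1, dur = 300) {
  cohort_spec(duration_s = dur, fs = 1000, seed = seed)
}

test_that("generated recordings are reproducible and truth is consistent", {
  g1 <- gen_recording(spec_small(3))
  g2 <- gen_recording(spec_small(3))
  expect_identical(g1$recording$samples, g2$recording$samples)
  expect_identical(g1$truth, g2$truth)
  tr <- g1$truth
  expect_true(all(tr$stop_s > tr$start_s))
  expect_true(all(diff(tr$start_s) > 0))
  expect_true(all(tr$start_s[-1] > tr$stop_s[-nrow(tr)]))  # non-overlapping
})

test_that("zero event rate gives stationary noise with empty truth", {
  g <- gen_recording(spec_small(4), event_rate = 0)
  expect_equal(nrow(g$truth), 0)
  x <- g$recording$samples[1, ]
  expect_equal(sd(x), 10, tolerance = 0.1)
})

test_that("impossible event rates are rejected with an explanation", {
  expect_error(gen_recording(spec_small(5), event_rate = 25), "event_rate too high")
})

test_that("fast-band power is elevated inside every truth event", {
  g <- gen_recording(spec_small(6, dur = 600))
  fs <- 1000
  x <- bandpass(g$recording$samples[1, ], fs, 12, 100)
  pwr <- function(a, b) mean(x[(floor(a * fs) + 1):floor(b * fs)]^2)
  tr <- g$truth
  outside <- mean(unlist(lapply(seq_len(nrow(tr)), function(i) {
    lo <- if (i == 1) 0 else tr$stop_s[i - 1] + 0.3
    x[(floor(lo * fs) + 1):floor((tr$start_s[i] - 0.3) * fs)]^2
  })))
  for (i in seq_len(nrow(tr))) {
    expect_gt(pwr(tr$start_s[i], tr$stop_s[i]), outside)
  }
})

test_that("most event power falls inside the declared carrier bands", {
  g <- gen_recording(spec_small(7, dur = 600))
  fs <- 1000
  ps <- concatenated_welch(g$recording$samples[1, ], fs, g$truth)
  # carriers are drawn from 5-11 and 16-39 Hz; compare to total 1-200 Hz power
  inband <- band_power(ps, c(4, 12)) + band_power(ps, c(15, 40))
  total <- band_power(ps, c(1, 200))
  expect_gt(inband / total, 0.8)
})

test_that("spike trains hit the target rate and lock with the set kappa", {
  # no events: homogeneous Poisson at 10^log10_rate
  empty <- gen_recording(spec_small(8), event_rate = 0)$truth
  s <- gen_spiketrain(empty, log10_rate = -0.61, seed = 1)
  rate <- 10^-0.61
  dur <- attr(empty, "duration_s")
  se <- sqrt(rate / dur)
  expect_lt(abs(firing_rate(s) - rate), 3 * se)
  # with events the marginal rate is still controlled
  g <- gen_recording(spec_small(9, dur = 900))
  s2 <- gen_spiketrain(g$truth, log10_rate = -0.3, kappa = 2, seed = 2)
  expect_lt(abs(firing_rate(s2) - 10^-0.3), 3 * sqrt(10^-0.3 / 900))
  # kappa = 0: phases uniform, PPC ~ 0
  s0 <- gen_spiketrain(g$truth, log10_rate = 0.7, kappa = 0, seed = 3)
  ph0 <- unlist(lapply(seq_len(nrow(g$truth)), function(i) {
    tt <- s0$times_s[s0$times_s >= g$truth$start_s[i] &
                       s0$times_s <= g$truth$stop_s[i]]
    neonosc:::.truth_phase(g$truth, i, tt)
  }))
  expect_gt(length(ph0), 3000)
  expect_lt(abs(ppc(ph0)), 0.01)
  # kappa = 2: PPC near the analytic value
  s4 <- gen_spiketrain(g$truth, log10_rate = 0.7, kappa = 2, seed = 4)
  ph2 <- unlist(lapply(seq_len(nrow(g$truth)), function(i) {
    tt <- s4$times_s[s4$times_s >= g$truth$start_s[i] &
                       s4$times_s <= g$truth$stop_s[i]]
    neonosc:::.truth_phase(g$truth, i, tt)
  }))
  expect_lt(abs(ppc(ph2) - (besselI(2, 1) / besselI(2, 0))^2), 0.03)
})

test_that("ramp sessions differ between tuned and untuned firing modes", {
  rs <- gen_ramp_session("tuned", n_trials = 30, seed = 26)
  h <- isi_histogram(rs$spikes)
  mode_bin <- h$bin_center_ms[which.max(h$mass)]
  expect_gte(mode_bin, 56)
  expect_lte(mode_bin, 64)
  for (mode in c("tuned", "untuned")) {
    r <- gen_ramp_session(mode, n_trials = 20, seed = 27)
    ep <- r$epochs
    pre <- mean(vapply(seq_len(nrow(ep)), function(i)
      firing_rate(r$spikes, c(ep$pre_start_s[i], ep$pre_stop_s[i])),
      numeric(1)))
    ramp <- mean(vapply(seq_len(nrow(ep)), function(i)
      firing_rate(r$spikes, c(ep$ramp_onset_s[i], ep$ramp_offset_s[i])),
      numeric(1)))
    expect_gt(ramp, pre)
    expect_equal(ep$ramp_offset_s - ep$ramp_onset_s, rep(3, nrow(ep)))
  }
  # untuned mode imposes no interval structure across 10-500 ms
  ru <- gen_ramp_session("untuned", n_trials = 400, seed = 28)
  hu <- isi_histogram(ru$spikes)
  expect_lt(max(hu$mass), 3 * median(hu$mass))
})

test_that("feature cohorts have the requested separation structure", {
  sp <- cohort_spec(n_per_group = 10, seed = 29)
  fc <- gen_feature_cohort(sp, effect_scale = 0)
  expect_equal(nrow(fc), 20)
  expect_equal(sum(fc$group == "control"), 10)
  expect_equal(ncol(fc), 2 + 5)
  # effect_scale shifts every feature by that many SD
  big <- gen_feature_cohort(cohort_spec(n_per_group = 200, seed = 30),
                            effect_scale = 2)
  d <- colMeans(big[big$group == "GE", -(1:2)]) -
    colMeans(big[big$group == "control", -(1:2)])
  expect_true(all(abs(d - 2) < 0.3))
  expect_error(gen_feature_cohort(cohort_spec(n_per_group = 1)), ">= 2")
})

test_that("behavior tables invert the discrimination-ratio formula", {
  b0 <- gen_behavior(5, mean_dr = c(g = 0), noise_sd = 0, seed = 31)
  expect_true(all(b0$discrimination_ratio == 0))
  b5 <- gen_behavior(5, mean_dr = c(g = 0.5), noise_sd = 0, seed = 31)
  expect_true(all(abs(b5$discrimination_ratio - 0.5) < 1e-12))
  expect_true(all(b5$t_novel_s >= 0 & b5$t_familiar_s >= 0))
  # Monte-Carlo mean within 3 SE
  bm <- gen_behavior(200, mean_dr = c(g = 0.3), noise_sd = 0.15, seed = 32)
  expect_lt(abs(mean(bm$discrimination_ratio) - 0.3), 3 * 0.15 / sqrt(200))
  expect_error(gen_behavior(5, mean_dr = c(g = 1.2)), "inside")
})

test_that("microglia stacks plant exactly the requested geometry", {
  g <- gen_microglia_stack(n_cells = 3, n_puncta_inside = 4,
                           n_puncta_outside = 2, dim = c(360, 360, 20),
                           cell_semi_axes_px = c(30, 22, 6), seed = 33)
  expect_equal(nrow(g$truth$cells), 3)
  expect_equal(sum(!is.na(g$truth$puncta$inside_cell)), 4)
  expect_equal(sum(is.na(g$truth$puncta$inside_cell)), 2)
  expect_true(all(g$truth$puncta$volume_px >= 100 &
                    g$truth$puncta$volume_px <= 500))
  # determinism
  g2 <- gen_microglia_stack(n_cells = 3, n_puncta_inside = 4,
                            n_puncta_outside = 2, dim = c(360, 360, 20),
                            cell_semi_axes_px = c(30, 22, 6), seed = 33)
  expect_identical(g$iba, g2$iba)
  expect_identical(g$vglut, g2$vglut)
  # unplaceable geometry errors out
  expect_error(gen_microglia_stack(n_cells = 40, dim = c(256, 256, 20)),
               "not placeable")
})

test_that("rasterized analytic shapes recover their area", {
  for (r in c(40, 60)) {
    m <- make_circle_mask(r)
    expect_lt(abs(sum(m) - pi * r^2) / (pi * r^2), 0.02)
  }
})
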