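#' Cohort specification for synthetic data
#'
#' Describes the simulated study conditions: group sizes, per-group firing
#' rates by layer (log10 spikes/s), band power multipliers and von Mises
#' phase-locking concentrations. Group defaults follow the reported
#' superficial-layer firing of controls (log10 -0.61 +/- 0.04 spikes/s) and
#' dual-hit GE animals (log10 -2.1 +/- 0.1), deep-layer firing (-0.95 and
#' -1.3), with reduced fast-band power and lost beta/gamma locking precision
#' in the GE group.
#'
#' @param n_per_group animals per group (>= 1).
#' @param duration_s recording duration per animal, seconds.
#' @param fs sampling rate in Hz; must exceed twice the highest synthesized
#'   frequency (carriers reach 40 Hz, background extends to `fs/2`).
#' @param seed master integer seed.
#' @param group_params named list (one entry per group) of lists with fields
#'   `log10_rate_sup`, `log10_rate_deep` (each `c(mean, sd)`),
#'   `band_power_scale` (named theta/beta/gamma multipliers, > 0) and `kappa`
#'   (named theta/beta/gamma von Mises concentrations, >= 0).
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_per_group = 15, duration_s = 1200, fs = 1000,
                        seed = 1, group_params = NULL) {
  if (is.null(group_params)) {
    group_params <- list(
      control = list(
        log10_rate_sup = c(-0.61, 0.04), log10_rate_deep = c(-0.95, 0.05),
        band_power_scale = c(theta = 1, beta = 1, gamma = 1),
        kappa = c(theta = 1, beta = 2, gamma = 1)),
      GE = list(
        log10_rate_sup = c(-2.1, 0.1), log10_rate_deep = c(-1.3, 0.2),
        band_power_scale = c(theta = 0.8, beta = 0.5, gamma = 0.5),
        kappa = c(theta = 1, beta = 0.2, gamma = 0.2))
    )
  }
  stopifnot(n_per_group >= 1, fs > 2 * 100, duration_s > 0)
  for (g in group_params) {
    stopifnot(all(g$band_power_scale > 0), all(g$kappa >= 0))
  }
  structure(list(n_per_group = as.integer(n_per_group),
                 duration_s = duration_s, fs = fs, seed = as.integer(seed),
                 group_params = group_params),
            class = "cohort_spec")
}

#' Generate a discontinuous neonatal LFP recording with ground truth
#'
#' Synthesizes the hallmark neonatal cortical pattern: spindle-shaped
#' oscillatory events, each a mixture of a theta (5-11 Hz) and a faster
#' beta-range (16-39 Hz) cosine carrier under a tapered-cosine envelope,
#' separated by network silence, riding on 1/f Gaussian background noise.
#' Event count is deterministic (`event_rate * duration / 60`), event onsets
#' are jittered around an even spacing, and the full truth (times, carrier
#' frequencies and phases, amplitudes) is returned for detector validation.
#'
#' @param spec a [cohort_spec()].
#' @param condition group label (selects band power multipliers).
#' @param event_rate events per minute (0 gives pure background noise).
#' @param duration_range event duration range in seconds, uniform; lower
#'   bound must exceed 1 s so truth events pass the detector's duration rule.
#' @param n_channels number of channels (shared events, per-channel amplitude
#'   factor and independent background).
#' @param peak_amplitude event peak amplitude, uV.
#' @param background_sd background noise SD, uV.
#' @param background_exponent 1/f^alpha slope of the background.
#' @param taper_s rise/fall ramp duration of the tapered-cosine event
#'   envelope, seconds; a fixed short ramp keeps event boundaries physically
#'   well-defined regardless of event duration.
#' @param seed integer seed (defaults to `spec$seed`).
#' @return List with `recording` (a [recording()]) and `truth` (event tibble
#'   with `start_s`, `stop_s`, `carrier_bands`, `peak_amplitude`,
#'   `theta_freq`, `beta_freq`, `theta_phase`, `beta_phase`; attributes
#'   `duration_s`, `fs`, `background_exponent`).
#' @export
gen_recording <- function(spec = cohort_spec(), condition = "control",
                          event_rate = 4, duration_range = c(1.5, 4),
                          n_channels = 2, peak_amplitude = 60,
                          background_sd = 10, background_exponent = 1,
                          taper_s = 0.1, seed = spec$seed) {
  stopifnot(duration_range[1] > 1, duration_range[2] >= duration_range[1])
  fs <- spec$fs
  dur <- spec$duration_s
  n <- round(dur * fs)
  set.seed(seed)

  n_ev <- round(event_rate * dur / 60)
  if (event_rate > 0 &&
      n_ev * (mean(duration_range) + 1) > 0.9 * dur) {
    stop("event_rate too high: ", n_ev, " events of mean duration ",
         mean(duration_range), " s cannot be placed in ", dur,
         " s without overlap")
  }
  gp <- spec$group_params[[condition]]
  scl <- gp$band_power_scale

  if (n_ev > 0) {
    durs <- stats::runif(n_ev, duration_range[1], duration_range[2])
    slot <- dur / n_ev
    base <- (seq_len(n_ev) - 1) * slot + 1
    jit_max <- pmax(0, (slot - durs - 2) / 2)
    starts <- base + stats::runif(n_ev, 0, jit_max)
    stops <- pmin(starts + durs, dur - 0.5)
    truth <- tibble::tibble(
      start_s = starts, stop_s = stops,
      carrier_bands = "theta+beta",
      peak_amplitude = peak_amplitude,
      theta_freq = stats::runif(n_ev, 5, 11),
      beta_freq = stats::runif(n_ev, 16, 39),
      theta_phase = stats::runif(n_ev, -pi, pi),
      beta_phase = stats::runif(n_ev, -pi, pi))
  } else {
    truth <- tibble::tibble(
      start_s = numeric(0), stop_s = numeric(0), carrier_bands = character(0),
      peak_amplitude = numeric(0), theta_freq = numeric(0),
      beta_freq = numeric(0), theta_phase = numeric(0), beta_phase = numeric(0))
  }

  ev_wave <- numeric(n)
  for (i in seq_len(nrow(truth))) {
    i0 <- floor(truth$start_s[i] * fs) + 1L
    i1 <- min(n, floor(truth$stop_s[i] * fs))
    tt <- (seq(i0, i1) - 1) / fs
    env <- .tukey(length(tt), min(1, 2 * taper_s / (length(tt) / fs)))
    a_th <- peak_amplitude * 0.6 * sqrt(scl[["theta"]])
    a_be <- peak_amplitude * 0.4 * sqrt(scl[["beta"]])
    ev_wave[i0:i1] <- env * (
      a_th * cos(2 * pi * truth$theta_freq[i] * tt + truth$theta_phase[i]) +
      a_be * cos(2 * pi * truth$beta_freq[i] * tt + truth$beta_phase[i]))
  }

  ch_gain <- stats::runif(n_channels, 0.8, 1.2)
  samples <- matrix(0, n_channels, n)
  for (c0 in seq_len(n_channels)) {
    samples[c0, ] <- ch_gain[c0] * ev_wave +
      background_sd * .pink_noise(n, fs, background_exponent)
  }
  rec <- recording(samples, fs, animal_id = paste0("synth", seed),
                   condition = condition)
  attr(truth, "duration_s") <- dur
  attr(truth, "fs") <- fs
  attr(truth, "background_exponent") <- background_exponent
  list(recording = rec, truth = truth)
}

# carrier phase of a truth event's locking band at times tt (cosine
# convention: phase 0 at carrier maxima)
.truth_phase <- function(truth, i, tt, band = "beta") {
  f <- if (band == "theta") truth$theta_freq[i] else truth$beta_freq[i]
  p0 <- if (band == "theta") truth$theta_phase[i] else truth$beta_phase[i]
  .wrap_phase(2 * pi * f * tt + p0)
}

#' Generate a phase-locked spike train for a synthetic recording
#'
#' Inhomogeneous Poisson spiking whose rate is elevated during oscillatory
#' events; within events, spikes are thinned against the locking band's
#' carrier phase with acceptance proportional to a von Mises density
#' (concentration `kappa`, preferred phase 0 = carrier maxima), so the spike
#' phase law is exactly von Mises while the marginal rate stays at the
#' requested value.
#'
#' @param truth truth tibble from [gen_recording()] (carries duration and
#'   carrier parameters).
#' @param log10_rate target overall firing rate, log10 spikes/s.
#' @param kappa von Mises concentration of the locking (0 = uniform phases).
#' @param lock_band `"theta"` or `"beta"` carrier to lock to.
#' @param event_rate_ratio ratio of within-event to outside-event rate.
#' @param seed integer seed.
#' @param id unit/site id.
#' @return A [spike_series()].
#' @export
gen_spiketrain <- function(truth, log10_rate, kappa = 2, lock_band = "beta",
                           event_rate_ratio = 10, seed = 1, id = "synth_unit") {
  stopifnot(is.finite(kappa), kappa >= 0)
  dur <- attr(truth, "duration_s")
  if (is.null(dur)) stop("truth tibble lacks a duration_s attribute")
  rate <- 10^log10_rate
  stopifnot(rate > 0)
  set.seed(seed)
  n_ev <- nrow(truth)
  if (n_ev == 0) {
    n_spk <- stats::rpois(1, rate * dur)
    return(spike_series(sort(stats::runif(n_spk, 0, dur)), dur, id))
  }
  af <- sum(truth$stop_s - truth$start_s) / dur
  c_out <- 1 / ((1 - af) + event_rate_ratio * af)
  rate_out <- c_out * rate
  rate_in <- event_rate_ratio * c_out * rate

  # outside-event spikes: homogeneous Poisson on the silent intervals
  bounds <- c(0, as.vector(rbind(truth$start_s, truth$stop_s)), dur)
  out_spk <- numeric(0)
  for (j in seq(1, length(bounds) - 1, by = 2)) {
    a <- bounds[j]; b <- bounds[j + 1]
    if (b > a) {
      k <- stats::rpois(1, rate_out * (b - a))
      out_spk <- c(out_spk, stats::runif(k, a, b))
    }
  }
  # within-event spikes with von Mises thinning against the carrier phase
  acc_mean <- besselI(kappa, 0) * exp(-kappa)  # mean acceptance over phase
  in_spk <- numeric(0)
  for (i in seq_len(n_ev)) {
    a <- truth$start_s[i]; b <- truth$stop_s[i]
    k <- stats::rpois(1, rate_in / acc_mean * (b - a))
    cand <- stats::runif(k, a, b)
    if (kappa > 0 && k > 0) {
      ph <- .truth_phase(truth, i, cand, lock_band)
      keep <- stats::runif(k) < exp(kappa * (cos(ph) - 1))
      cand <- cand[keep]
    } else if (kappa > 0) {
      cand <- cand[0]
    }
    in_spk <- c(in_spk, cand)
  }
  times <- sort(unique(c(out_spk, in_spk)))
  spike_series(times, dur, id)
}

#' Generate an optogenetic ramp-stimulation session
#'
#' Each trial is `pre_s` of baseline, a 3-s linearly increasing light ramp
#' and `post_s` of baseline. The LFP gains a beta-band oscillation whose
#' amplitude grows linearly along the ramp; firing increases during the ramp
#' in both modes. In `"tuned"` mode, during-ramp spiking is a near-regular
#' discharge at the preferred ~60-ms inter-spike interval (the 16.7-Hz
#' population rhythm of frequency-tuned superficial pyramidal neurons),
#' starting once ramp power crosses threshold; in `"untuned"` mode it is an
#' inhomogeneous Poisson train with no imposed interval.
#'
#' @param mode `"tuned"` or `"untuned"`.
#' @param n_trials number of ramp sweeps.
#' @param fs sampling rate, Hz.
#' @param pre_s,post_s baseline before/after each ramp, seconds (>= 1.5).
#' @param ramp_s ramp duration, seconds (protocol value 3 s).
#' @param isi_ms preferred inter-spike interval in tuned mode, ms.
#' @param isi_jitter_ms SD of timing jitter around the preferred interval.
#' @param baseline_rate baseline firing rate, spikes/s.
#' @param stim_freq_hz frequency of the light-evoked oscillation.
#' @param stim_amplitude peak oscillation amplitude at ramp end, uV.
#' @param background_sd background noise SD, uV.
#' @param seed integer seed.
#' @return List with `recording`, `spikes` (a [spike_series()]) and `epochs`
#'   (tibble: `trial`, `ramp_onset_s`, `ramp_offset_s`, `pre_start_s`,
#'   `pre_stop_s`, `stim_start_s`, `stim_stop_s`).
#' @export
gen_ramp_session <- function(mode = c("tuned", "untuned"), n_trials = 30,
                             fs = 1000, pre_s = 2, post_s = 2, ramp_s = 3,
                             isi_ms = 60, isi_jitter_ms = 2,
                             baseline_rate = 0.5,
                             stim_freq_hz = 20, stim_amplitude = 40,
                             background_sd = 10, seed = 1) {
  mode <- match.arg(mode)
  stopifnot(pre_s >= 1.5, post_s >= 1.5, ramp_s == 3)
  set.seed(seed)
  trial_s <- pre_s + ramp_s + post_s
  dur <- n_trials * trial_s
  n <- round(dur * fs)
  x <- background_sd * .pink_noise(n, fs, 1)
  epochs <- tibble::tibble(
    trial = seq_len(n_trials),
    ramp_onset_s = (seq_len(n_trials) - 1) * trial_s + pre_s,
    ramp_offset_s = (seq_len(n_trials) - 1) * trial_s + pre_s + ramp_s)
  epochs$pre_start_s <- epochs$ramp_onset_s - 1.5
  epochs$pre_stop_s <- epochs$ramp_onset_s
  epochs$stim_start_s <- epochs$ramp_offset_s - 1.5
  epochs$stim_stop_s <- epochs$ramp_offset_s

  spikes <- numeric(0)
  for (tr in seq_len(n_trials)) {
    on <- epochs$ramp_onset_s[tr]; off <- epochs$ramp_offset_s[tr]
    i0 <- floor(on * fs) + 1L; i1 <- floor(off * fs)
    tt <- (seq(i0, i1) - 1) / fs - on
    ph <- stats::runif(1, -pi, pi)
    x[i0:i1] <- x[i0:i1] +
      stim_amplitude * (tt / ramp_s) * cos(2 * pi * stim_freq_hz * tt + ph)
    # baseline spiking over the whole trial
    t0 <- (tr - 1) * trial_s
    k <- stats::rpois(1, baseline_rate * trial_s)
    spikes <- c(spikes, stats::runif(k, t0, t0 + trial_s))
    if (mode == "tuned") {
      t_sp <- on + 0.4 * ramp_s  # discharge initiates once power is high
      while (TRUE) {
        t_sp <- t_sp + (isi_ms + stats::rnorm(1, 0, isi_jitter_ms)) / 1000
        if (t_sp >= off) break
        spikes <- c(spikes, t_sp)
      }
    } else {
      # renewal process with uniform ISIs over the analysis range: elevated
      # ramp firing with no imposed preferred interval (flat ISI mass)
      t_sp <- on + stats::runif(1, 0, 0.1)
      while (TRUE) {
        t_sp <- t_sp + stats::runif(1, 0.01, 0.5)
        if (t_sp >= off) break
        spikes <- c(spikes, t_sp)
      }
    }
  }
  spikes <- sort(unique(pmin(pmax(spikes, 0), dur - 1e-6)))
  list(recording = recording(matrix(x, 1, n), fs, condition = mode),
       spikes = spike_series(spikes, dur, id = paste0("ramp_", mode)),
       epochs = epochs)
}
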