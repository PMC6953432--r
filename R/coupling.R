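#' Instantaneous phase in a frequency band
#'
#' Zero-phase band-pass followed by the analytic-signal (Hilbert)
#' construction. Phase is 0 at local maxima of the band-limited oscillation
#' and lies in `(-pi, pi]`.
#'
#' @param lfp numeric LFP vector (uV).
#' @param fs sampling rate, Hz.
#' @param band `c(lo, hi)` in Hz or a band name (`"theta"`, `"beta"`,
#'   `"gamma"`).
#' @param order Butterworth order for the band-pass.
#' @return Phase vector in radians, same length as `lfp`.
#' @export
band_phase <- function(lfp, fs, band = "beta", order = 3) {
  if (is.character(band)) band <- .BANDS[[match.arg(band, names(.BANDS))]]
  if (band[2] >= fs / 2) stop("band upper edge at or above Nyquist")
  .analytic_phase(bandpass(lfp, fs, band[1], band[2], order = order))
}

#' Pairwise phase consistency
#'
#' The mean cosine of the angular distance over all pairs of spike phases:
#' `(2 / (n (n-1))) * sum_{j<k} cos(theta_j - theta_k)`. Unlike the resultant
#' length, PPC is free of sample-size bias; its population value for von
#' Mises locking with concentration kappa is `(I1(kappa)/I0(kappa))^2`.
#' Computed through the closed form `(|sum e^{i theta}|^2 - n) / (n (n-1))`,
#' which equals the pairwise sum exactly.
#'
#' @param phases numeric vector of spike phases, radians; `n >= 2`.
#' @return PPC in `[-1/(n-1), 1]`.
#' @export
ppc <- function(phases) {
  n <- length(phases)
  if (n < 2) stop("PPC requires at least 2 spike phases")
  r2 <- sum(cos(phases))^2 + sum(sin(phases))^2
  (r2 - n) / (n * (n - 1))
}

# brute-force pairwise PPC; independent oracle used by the tests
.ppc_pairwise <- function(phases) {
  n <- length(phases)
  d <- outer(phases, phases, "-")
  (sum(cos(d)) - n) / (n * (n - 1))
}

#' Spike-triggered relative LFP power
#'
#' For each spike, the spike-triggered power spectrum is the Welch estimate
#' of a 200-ms window centered on the spike (40-ms Hann segments with 50%
#' overlap, zero-padded to the window length so values are reported on a
#' 5-Hz grid), and the baseline power is the average of the spectra of two
#' windows 100-300 ms and 200-400 ms before the spike. Because the baseline
#' enters a denominator, the raw per-spike ratio carries the inverse-
#' chi-square bias `nu/(nu - 2)`; the estimator applies the exact
#' `(nu - 2)/nu` correction, with the effective baseline degrees of freedom
#' `nu` derived from the Welch segment geometry (Percival-Walden) and the
#' half-overlap of the two printed baseline windows.
#' The result is the across-spike mean of
#' `(Power_spike - Power_baseline) / Power_baseline` per frequency;
#' positive values mean spikes occur during elevated band power. Spikes
#' without a complete 400-ms pre-history or 100-ms post-window are skipped
#' and counted.
#'
#' @param lfp numeric LFP vector (uV).
#' @param fs sampling rate, Hz.
#' @param spikes a [spike_series()] or numeric spike-time vector (s).
#' @param window_s spike-centered window length, seconds.
#' @return A `coupling_result`: tibble with `frequency_hz` and `st_rel_power`,
#'   plus attributes `band_summary` (named mean relative power over beta
#'   12-30 and gamma 30-100 Hz), `n_spikes` (used) and `n_skipped`.
#' @export
spike_triggered_relative_power <- function(lfp, fs, spikes, window_s = 0.2) {
  t <- if (inherits(spikes, "spike_series")) spikes$times_s else spikes
  half <- window_s / 2
  t_end <- length(lfp) / fs
  ok <- t - 0.4 >= 0 & t + half <= t_end
  n_skip <- sum(!ok)
  t <- t[ok]
  if (!length(t)) stop("no spike has complete baseline and spike windows inside the recording")
  win <- round(window_s * fs)
  seg <- round(window_s / 5 * fs)  # 40-ms sub-segments, 50% overlap
  # effective dof of the averaged baseline: per-window Welch dof for K
  # Hann segments at 50% overlap (Percival-Walden 36K^2/(19K-1)), and the
  # two baseline windows share half their span (~K/2 shared segments), so
  # averaging them scales dof by 2/(1 + rho) with rho ~ the shared fraction
  k_seg <- floor((win - seg) / (seg / 2)) + 1
  nu_w <- 36 * k_seg^2 / (19 * k_seg - 1)
  rho <- (k_seg / 2) / k_seg
  nu_b <- 2 * nu_w / (1 + rho)
  bias_corr <- (nu_b - 2) / nu_b
  grab <- function(center) {
    i0 <- round(center * fs) - win %/% 2
    lfp[(i0 + 1):(i0 + win)]
  }
  wpsd <- function(v) welch_psd(v, fs, seg, overlap = 0.5, nfft = win)
  freq <- NULL
  acc <- NULL
  for (ti in t) {
    ps_spike <- wpsd(grab(ti))
    ps_b1 <- wpsd(grab(ti - 0.2))   # 100-300 ms pre
    ps_b2 <- wpsd(grab(ti - 0.3))   # 200-400 ms pre
    base <- (ps_b1$psd + ps_b2$psd) / 2
    rel <- bias_corr * ps_spike$psd / base - 1
    rel[!is.finite(rel)] <- NA_real_
    keep <- ps_spike$frequency_hz > 0  # the demeaned DC bin carries no signal
    if (is.null(acc)) {
      freq <- ps_spike$frequency_hz[keep]
      acc <- matrix(rel[keep], nrow = 1)
    } else {
      acc <- rbind(acc, rel[keep])
    }
  }
  strp <- colMeans(acc, na.rm = TRUE)
  res <- tibble::tibble(frequency_hz = freq, st_rel_power = strp)
  summ <- c(
    beta = mean(strp[freq >= 12 & freq < 30]),
    gamma = mean(strp[freq >= 30 & freq < 100])
  )
  structure(res, band_summary = summ, n_spikes = length(t),
            n_skipped = n_skip, class = c("coupling_result", class(res)))
}
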