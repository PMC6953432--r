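.BANDS <- list(theta = c(4, 12), beta = c(12, 30), gamma = c(30, 100))

#' Power spectrum of concatenated oscillatory windows
#'
#' Each detected oscillation contributes `floor(duration)` non-overlapping
#' 1-s windows; Welch's method averages the Hann-tapered periodograms of all
#' windows (1 Hz frequency resolution). Network silence between events never
#' enters the estimate, so the spectrum characterizes oscillatory activity
#' only.
#'
#' @param x numeric signal vector (uV), the LFP band.
#' @param fs sampling rate, Hz.
#' @param events event tibble with `start_s` / `stop_s` columns
#'   ([detect_oscillations()] output or ground-truth events).
#' @return A `power_spectrum`: tibble with `frequency_hz`, `psd` (uV^2/Hz),
#'   plus a `band_powers` attribute with theta (4-12), beta (12-30) and gamma
#'   (30-100 Hz) powers in uV^2.
#' @export
concatenated_welch <- function(x, fs, events) {
  if (is.null(events) || nrow(events) == 0) {
    stop("no oscillatory events: power of network oscillations is undefined")
  }
  seg <- round(fs)  # 1-s segments
  wins <- list()
  for (i in seq_len(nrow(events))) {
    n_win <- floor(events$stop_s[i] - events$start_s[i])
    if (n_win < 1) stop("every event must last at least 1 s")
    i0 <- floor(events$start_s[i] * fs)
    for (j in seq_len(n_win)) {
      idx <- (i0 + (j - 1) * seg + 1):(i0 + j * seg)
      idx <- idx[idx <= length(x)]
      if (length(idx) == seg) wins[[length(wins) + 1]] <- x[idx]
    }
  }
  if (!length(wins)) stop("no complete 1-s window inside the recording")
  ps <- welch_psd(unlist(wins), fs, seg_len = seg)
  new_power_spectrum(ps)
}

new_power_spectrum <- function(ps) {
  bp <- vapply(.BANDS, function(b) .band_integral(ps, b[1], b[2]), numeric(1))
  structure(ps, band_powers = bp, class = c("power_spectrum", class(ps)))
}

# left-closed Riemann sum over [lo, hi): satisfies additivity of disjoint
# bands and the convention that a tone exactly at 30 Hz counts as gamma
.band_integral <- function(ps, lo, hi) {
  df <- diff(ps$frequency_hz[1:2])
  sel <- ps$frequency_hz >= lo & ps$frequency_hz < hi
  if (!any(sel)) stop("band [", lo, ", ", hi, ") is empty for this spectrum")
  sum(ps$psd[sel]) * df
}

#' Band power from a spectrum
#'
#' Integrates the PSD over a named band (`"theta"` 4-12, `"beta"` 12-30,
#' `"gamma"` 30-100 Hz) or a numeric `c(lo, hi)`. Band edges are half-open
#' `[lo, hi)` so adjacent bands never double-count an edge frequency.
#'
#' @param spectrum a `power_spectrum` (or any tibble with `frequency_hz`,
#'   `psd`).
#' @param band band name or numeric length-2 vector, Hz.
#' @return Band power in uV^2.
#' @export
band_power <- function(spectrum, band) {
  if (is.character(band)) {
    band <- .BANDS[[match.arg(band, names(.BANDS))]]
  }
  stopifnot(length(band) == 2, band[1] < band[2])
  .band_integral(spectrum, band[1], band[2])
}

#' Stimulation modulation index
#'
#' Bounded contrast `(stim - pre) / (stim + pre)` of band power during the
#' last 1.5 s of a light ramp versus the 1.5 s preceding stimulation onset;
#' 0 means no modulation, 1 means power appears only during stimulation.
#'
#' @param pre_power,stim_power band powers in uV^2 (non-negative).
#' @return Modulation index in `[-1, 1]`; `NA` (flagged undefined) when both
#'   powers are zero.
#' @export
modulation_index <- function(pre_power, stim_power) {
  stopifnot(pre_power >= 0, stim_power >= 0)
  tot <- pre_power + stim_power
  ifelse(tot == 0, NA_real_, (stim_power - pre_power) / tot)
}

#' Pre- and during-stimulation band power for a ramp epoch
#'
#' Welch band power (0.75-s Hann segments, no overlap, i.e. two segments per
#' 1.5-s window) in the window preceding ramp onset and the last 1.5 s of the
#' ramp.
#'
#' @param x numeric LFP vector (uV).
#' @param fs sampling rate, Hz.
#' @param epoch one-row tibble (or list) with `ramp_onset_s`, `ramp_offset_s`.
#' @param band band name or `c(lo, hi)` Hz.
#' @param window_s analysis window length, seconds.
#' @return Tibble with `pre`, `stim` (uV^2) and `modulation_index`.
#' @export
stim_power_pair <- function(x, fs, epoch, band = "beta", window_s = 1.5) {
  on <- epoch$ramp_onset_s[1]; off <- epoch$ramp_offset_s[1]
  t_end <- length(x) / fs
  if (on - window_s < 0 || off > t_end) {
    stop("stimulation windows extend beyond the recording")
  }
  seg <- round(window_s / 2 * fs)
  cut <- function(a, b) x[(floor(a * fs) + 1):floor(b * fs)]
  pre_ps <- welch_psd(cut(on - window_s, on), fs, seg)
  stim_ps <- welch_psd(cut(off - window_s, off), fs, seg)
  pre <- band_power(pre_ps, band)
  stim <- band_power(stim_ps, band)
  tibble::tibble(pre = pre, stim = stim,
                 modulation_index = modulation_index(pre, stim))
}
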