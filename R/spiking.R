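#' Spike time series
#'
#' Sorted spike (or multi-unit event) times for one recording site/unit.
#'
#' @param times_s numeric vector of spike times, seconds; sorted strictly
#'   increasing within `[0, duration_s]`.
#' @param duration_s duration of the underlying recording, seconds.
#' @param id unit or site identifier.
#' @return An object of class `spike_series`.
#' @export
spike_series <- function(times_s, duration_s, id = "site1") {
  times_s <- as.numeric(times_s)
  stopifnot(!is.unsorted(times_s, strictly = TRUE) || length(times_s) < 2,
            all(times_s >= 0), all(times_s <= duration_s), duration_s > 0)
  structure(list(times_s = times_s, duration_s = duration_s, id = id),
            class = "spike_series")
}

#' @export
print.spike_series <- function(x, ...) {
  cat(sprintf("<spike_series> %s: %d spikes over %.1f s (%.3f spikes/s)\n",
              x$id, length(x$times_s), x$duration_s,
              length(x$times_s) / x$duration_s))
  invisible(x)
}

# prominence of peaks (indices pk) in a signal y: height above the higher of
# the two key saddles toward the nearest higher peaks (standard definition)
.peak_prominence <- function(y, pk) {
  o <- order(y[pk], decreasing = TRUE)
  prom <- numeric(length(pk))
  for (j in o) {
    p <- pk[j]; hp <- y[p]
    # left: lowest point between p and the nearest sample at least as high
    left <- if (p > 1) {
      i <- p - 1
      higher <- which(y[seq_len(p - 1)] > hp)
      lo <- if (length(higher)) max(higher) + 1L else 1L
      min(y[lo:(p - 1)], hp)
    } else hp
    right <- if (p < length(y)) {
      higher <- which(y[(p + 1):length(y)] > hp)
      hi <- if (length(higher)) p + min(higher) - 1L else length(y)
      min(y[(p + 1):hi], hp)
    } else hp
    prom[j] <- hp - max(left, right)
  }
  prom
}

#' Detect multi-unit activity from the high-pass band
#'
#' Spikes are the peaks of negative deflections of the 500-5000 Hz filtered
#' signal exceeding `threshold_sd` (default 5) standard deviations, kept only
#' when their prominence (computed on the inverted trace) is larger than half
#' the peak itself. A short dead time prevents double-counting multiphasic
#' waveforms.
#'
#' @param x numeric MUA-band signal (uV).
#' @param fs sampling rate, Hz.
#' @param threshold_sd threshold in SD units (default 5).
#' @param robust_sd use a median-based SD estimate (`mad`) instead of the
#'   plain standard deviation; default `FALSE` (plain SD of the full trace),
#'   available because heavy spiking inflates the plain SD.
#' @param dead_time_s minimum separation between accepted spikes, seconds.
#' @return A [spike_series()] of spike times (sample of each minimum / fs).
#' @export
detect_mua <- function(x, fs, threshold_sd = 5, robust_sd = FALSE,
                       dead_time_s = 0.001) {
  s <- if (robust_sd) stats::mad(x) else stats::sd(x)
  if (!is.finite(s) || s == 0) stop("signal has zero variance; cannot set a spike threshold")
  thr <- threshold_sd * s
  y <- -x  # work on the inverted trace: spikes become positive peaks
  n <- length(y)
  cand <- which(y > thr)
  cand <- cand[cand > 1 & cand < n]
  cand <- cand[y[cand] >= y[cand - 1] & y[cand] > y[cand + 1]]
  if (length(cand)) {
    prom <- .peak_prominence(y, cand)
    cand <- cand[prom > y[cand] / 2]
  }
  # dead time: greedy by amplitude
  if (length(cand) > 1) {
    keep <- logical(length(cand))
    o <- order(y[cand], decreasing = TRUE)
    taken <- rep(FALSE, n)
    dt <- max(1L, round(dead_time_s * fs))
    for (j in o) {
      p <- cand[j]
      if (!taken[p]) {
        keep[j] <- TRUE
        lo <- max(1L, p - dt); hi <- min(n, p + dt)
        taken[lo:hi] <- TRUE
      }
    }
    cand <- sort(cand[keep])
  }
  spike_series((cand - 1L) / fs, duration_s = n / fs, id = "mua")
}

#' Mean firing rate in a window
#'
#' Total spike count divided by the duration of the analyzed time window.
#'
#' @param spikes a [spike_series()] or numeric vector of spike times (s).
#' @param window `c(t0, t1)` seconds; defaults to the full series duration.
#' @param log10 also return the log10-transformed rate (used as a cohort
#'   feature; `-Inf` for empty windows).
#' @return Firing rate in spikes/s (with attribute `log10_rate` when
#'   requested).
#' @export
firing_rate <- function(spikes, window = NULL, log10 = FALSE) {
  t <- if (inherits(spikes, "spike_series")) spikes$times_s else spikes
  if (is.null(window)) {
    stopifnot(inherits(spikes, "spike_series"))
    window <- c(0, spikes$duration_s)
  }
  stopifnot(window[2] > window[1])
  rate <- sum(t >= window[1] & t < window[2]) / diff(window)
  if (log10) attr(rate, "log10_rate") <- log10(rate)
  rate
}

#' Inter-spike-interval histogram
#'
#' ISIs at 2-ms resolution, normalized to the total number of ISIs (all
#' intervals, not only those displayed); the returned range is restricted to
#' 10-500 ms, so the returned mass may sum to less than 1 when intervals fall
#' outside that range.
#'
#' @param spikes a [spike_series()] or numeric vector of spike times (s).
#' @param bin_ms bin width, ms.
#' @param range_ms displayed/analyzed range, ms.
#' @return Tibble with `bin_center_ms` and `mass`.
#' @export
isi_histogram <- function(spikes, bin_ms = 2, range_ms = c(10, 500)) {
  t <- if (inherits(spikes, "spike_series")) spikes$times_s else spikes
  if (length(t) < 2) stop("at least 2 spikes are required for an ISI histogram")
  isi <- diff(t) * 1000
  breaks <- seq(0, max(range_ms[2], ceiling(max(isi) / bin_ms) * bin_ms), by = bin_ms)
  counts <- graphics::hist(isi, breaks = breaks, plot = FALSE)$counts
  centers <- breaks[-1] - bin_ms / 2
  mass <- counts / length(isi)
  sel <- centers >= range_ms[1] & centers <= range_ms[2]
  tibble::tibble(bin_center_ms = centers[sel], mass = mass[sel])
}
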