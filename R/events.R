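#' Sliding root-mean-square envelope
#'
#' Centered sliding RMS of a band-passed (1-100 Hz) signal, the quantity whose
#' supra-threshold deflections define discontinuous network oscillations in
#' neonatal cortex. Computed with a cumulative-sum running mean of the squared
#' signal; edges use the partial window.
#'
#' @param x numeric signal vector (uV), band-passed 1-100 Hz.
#' @param fs sampling rate, Hz.
#' @param window_ms RMS window length in milliseconds (default 200 ms: long
#'   enough to smooth individual gamma cycles, short against the 1-s minimum
#'   event duration).
#' @param align window alignment: `"centered"` (default), `"causal"` (window
#'   trails the current sample) or `"anticausal"` (window leads); the
#'   one-sided variants localize power onsets/offsets without the half-window
#'   smear of the centered window.
#' @return Numeric envelope vector (uV), same length as `x`.
#' @export
rms_envelope <- function(x, fs, window_ms = 200,
                         align = c("centered", "causal", "anticausal")) {
  align <- match.arg(align)
  stopifnot(window_ms > 0)
  w <- max(1L, round(window_ms / 1000 * fs))
  n <- length(x)
  if (w > n) stop("RMS window longer than the signal")
  cs <- cumsum(c(0, x^2))
  half <- switch(align, centered = w %/% 2, causal = w - 1L, anticausal = 0L)
  lo <- pmax(0L, seq_len(n) - 1L - half)
  hi <- pmin(n, seq_len(n) - 1L + (w - half))
  sqrt((cs[hi + 1L] - cs[lo + 1L]) / (hi - lo))
}

#' Gaussian-fit RMS threshold
#'
#' Fits a Gaussian, by nonlinear least squares, to the histogram of envelope
#' values restricted to the range from 0 up to the histogram's global maximum,
#' i.e. to the silence-dominated left flank; the event tail to the right of
#' the mode is excluded from the fit. The detection threshold is
#' `mu + k * sigma` of the fitted curve.
#'
#' @param envelope non-negative RMS envelope values (uV).
#' @param n_bins number of histogram bins over `[0, max(envelope)]`.
#' @param k threshold multiplier in fitted-SD units (default 2); the single
#'   most result-sensitive free parameter of the detector.
#' @param mode_def how to read "global maximum of the histogram": `"mode"`
#'   (the peak bin; default) or `"max"` (the largest envelope value, i.e. the
#'   full histogram).
#' @return Threshold in uV, with the fitted `mu` and `sigma` as attributes.
#' @export
fit_rms_threshold <- function(envelope, n_bins = 100, k = 2,
                              mode_def = c("mode", "max")) {
  mode_def <- match.arg(mode_def)
  stopifnot(length(envelope) > 0, all(envelope >= 0), n_bins >= 5)
  # re-bin finer when the silence mode is narrow against the full range
  # (strong events stretch the histogram; the fit needs a resolved left flank)
  for (nb in n_bins * c(1, 4, 16, 64)) {
    h <- graphics::hist(envelope,
                        breaks = seq(0, max(envelope), length.out = nb + 1),
                        plot = FALSE)
    counts <- h$counts
    centers <- h$mids
    upper <- if (mode_def == "mode") which.max(counts) else length(counts)
    sel <- seq_len(upper)
    if (sum(counts[sel] > 0) >= 5) break
  }
  if (sum(counts[sel] > 0) < 3) stop("degenerate envelope histogram: too few occupied bins for a Gaussian fit")
  df <- data.frame(xc = centers[sel], yc = counts[sel])
  mu0 <- centers[which.max(counts)]
  sigma0 <- max(stats::sd(envelope[envelope <= 2 * mu0]), diff(centers[1:2]))
  fit <- minpack.lm::nlsLM(
    yc ~ A * exp(-(xc - mu)^2 / (2 * sigma^2)),
    data = df,
    start = list(A = max(counts), mu = mu0, sigma = sigma0),
    lower = c(A = 0, mu = 0, sigma = 1e-12),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  cf <- stats::coef(fit)
  structure(unname(cf["mu"] + k * abs(cf["sigma"])),
            mu = unname(cf["mu"]), sigma = unname(abs(cf["sigma"])), k = k)
}

# merge intervals closer than gap_s, given start/stop vectors sorted by start
.merge_intervals <- function(start, stop, gap_s) {
  if (length(start) == 0) return(list(start = numeric(0), stop = numeric(0)))
  ms <- start[1]; me <- stop[1]
  out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] - me < gap_s) {
      me <- max(me, stop[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- stop[i]
    }
  }
  list(start = c(out_s, ms), stop = c(out_e, me))
}

#' Detect discontinuous oscillatory events
#'
#' Unsupervised detector for spindle-shaped network oscillations: the RMS
#' envelope of the 1-100 Hz signal is thresholded at the Gaussian-fit level
#' ([fit_rms_threshold()]), supra-threshold intervals closer than 200 ms are
#' merged into one oscillation, and only oscillations lasting more than 1 s
#' are kept (merging is applied before the duration filter).
#'
#' @param x numeric signal vector (uV), band-passed 1-100 Hz.
#' @param fs sampling rate, Hz.
#' @param k threshold multiplier (see [fit_rms_threshold()]).
#' @param window_ms RMS window, ms.
#' @param min_duration_s minimum event duration, seconds (events of exactly
#'   this duration are excluded; the rule is strictly greater).
#' @param merge_gap_s gap below which two oscillations count as one, seconds.
#' @param refine_edges re-localize each interval's onset with a causal
#'   (trailing) RMS window and its offset with an anti-causal (leading)
#'   window of the same length; the centered detection window alone smears
#'   boundaries outward by up to half its length.
#' @param channel channel id stored in the output.
#' @param threshold optional fixed threshold in uV, bypassing the Gaussian fit.
#' @return Tibble of events: `channel`, `start_s`, `stop_s`, `duration_s`,
#'   `peak_amplitude` (max absolute filtered deflection, uV), `mean_rms` (uV).
#'   Attributes record the threshold used.
#' @export
detect_oscillations <- function(x, fs, k = 2, window_ms = 200,
                                min_duration_s = 1, merge_gap_s = 0.2,
                                refine_edges = TRUE,
                                channel = 1L, threshold = NULL) {
  env <- rms_envelope(x, fs, window_ms)
  thr <- threshold %||% tryCatch(fit_rms_threshold(env, k = k),
                                 error = function(e) Inf)
  empty <- tibble::tibble(
    channel = integer(0), start_s = numeric(0), stop_s = numeric(0),
    duration_s = numeric(0), peak_amplitude = numeric(0), mean_rms = numeric(0))
  above <- env > thr
  if (!any(above)) return(structure(empty, threshold = thr))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- r$values
  i0 <- starts[on]
  i1 <- ends[on]
  if (isTRUE(refine_edges)) {
    env_c <- rms_envelope(x, fs, window_ms, align = "causal")
    env_a <- rms_envelope(x, fs, window_ms, align = "anticausal")
    for (j in seq_along(i0)) {
      up <- which(env_c[i0[j]:i1[j]] > thr)
      new0 <- if (length(up)) i0[j] + up[1] - 1L else i0[j]
      up <- which(env_a[i0[j]:i1[j]] > thr)
      new1 <- if (length(up)) i0[j] + up[length(up)] - 1L else i1[j]
      if (new1 > new0) {
        i0[j] <- new0
        i1[j] <- new1
      }
    }
  }
  s0 <- (i0 - 1L) / fs
  s1 <- i1 / fs
  m <- .merge_intervals(s0, s1, merge_gap_s)
  keep <- (m$stop - m$start) > min_duration_s
  if (!any(keep)) return(structure(empty, threshold = thr))
  s0 <- m$start[keep]; s1 <- m$stop[keep]
  peak <- mapply(function(a, b) {
    idx <- (floor(a * fs) + 1L):min(length(x), ceiling(b * fs))
    max(abs(x[idx]))
  }, s0, s1)
  mrms <- mapply(function(a, b) {
    idx <- (floor(a * fs) + 1L):min(length(env), ceiling(b * fs))
    mean(env[idx])
  }, s0, s1)
  structure(
    tibble::tibble(channel = as.integer(channel), start_s = s0, stop_s = s1,
                   duration_s = s1 - s0, peak_amplitude = peak, mean_rms = mrms),
    threshold = thr)
}

#' Summary statistics of detected oscillations
#'
#' @param events event tibble from [detect_oscillations()].
#' @param total_duration_s recording duration, seconds.
#' @return One-row tibble: `n_events`, `occurrence` (events/min),
#'   `mean_duration` (s), `mean_amplitude` (uV), `active_fraction`. Means are
#'   `NA` when no events were detected.
#' @export
summarize_events <- function(events, total_duration_s) {
  stopifnot(total_duration_s > 0)
  n <- nrow(events)
  tibble::tibble(
    n_events = n,
    occurrence = n / (total_duration_s / 60),
    mean_duration = if (n) mean(events$duration_s) else NA_real_,
    mean_amplitude = if (n) mean(events$peak_amplitude) else NA_real_,
    active_fraction = if (n) sum(events$duration_s) / total_duration_s else 0
  )
}
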