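#' Multichannel extracellular recording container
#'
#' Bundles a channels-by-time sample matrix (uV) with its sampling rate and
#' per-channel metadata (cortical layer, depth). All signal operations in the
#' package either take a bare numeric vector plus `fs`, or a `recording`.
#'
#' @param samples numeric matrix, channels x time, in uV (a vector is treated
#'   as one channel).
#' @param fs sampling rate in Hz.
#' @param channels tibble with one row per channel; columns `id`, `layer`
#'   (`"superficial"` or `"deep"`), `depth_um`. Generated automatically if
#'   missing.
#' @param animal_id,condition free-form metadata labels.
#' @return An object of class `recording`.
#' @export
recording <- function(samples, fs, channels = NULL, animal_id = NA_character_,
                      condition = NA_character_) {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1)
  stopifnot(is.matrix(samples), fs > 0, all(is.finite(samples)))
  n_ch <- nrow(samples)
  if (is.null(channels)) {
    channels <- tibble::tibble(
      id = seq_len(n_ch),
      layer = rep(c("superficial", "deep"), length.out = n_ch),
      depth_um = seq(100, by = 100, length.out = n_ch)
    )
  }
  stopifnot(nrow(channels) == n_ch)
  structure(
    list(samples = samples, fs = fs, channels = channels,
         animal_id = animal_id, condition = condition),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf(
    "<recording> %d channel(s), %.1f s @ %g Hz (animal %s, condition %s)\n",
    nrow(x$samples), ncol(x$samples) / x$fs, x$fs, x$animal_id, x$condition))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec a [recording()].
#' @export
duration_s <- function(rec) ncol(rec$samples) / rec$fs

# zero-phase filtering: reflect-pad by 3 filter lengths, run the IIR filter
# forward and backward, trim. signal::filtfilt does no padding, which leaves
# transients on short segments.
.filtfilt_pad <- function(b, a, x) {
  # at least 3 filter lengths; more on long signals to damp slow transients
  npad <- min(length(x) - 1, max(3 * max(length(a), length(b)), 256))
  pre <- 2 * x[1] - x[(npad + 1):2]
  post <- 2 * x[length(x)] - x[(length(x) - 1):(length(x) - npad)]
  xe <- c(pre, x, post)
  y <- signal::filter(b, a, xe)
  y <- rev(as.numeric(signal::filter(b, a, rev(as.numeric(y)))))
  y[(npad + 1):(npad + length(x))]
}

#' Zero-phase Butterworth band-pass filter
#'
#' Third-order Butterworth by default, applied forward and backward so the
#' output is phase-preserving (zero lag in the passband). The LFP band in this
#' pipeline is 4-100 Hz, the event-detection band 1-100 Hz and the MUA band
#' 500-5000 Hz.
#'
#' @param x numeric signal vector (uV).
#' @param fs sampling rate, Hz.
#' @param low,high band edges in Hz; must satisfy `0 < low < high < fs/2`.
#' @param order filter order (default 3).
#' @return Filtered vector, same length as `x`.
#' @export
bandpass <- function(x, fs, low, high, order = 3) {
  stopifnot(is.numeric(x), length(x) > 10, order >= 1)
  if (!(low > 0 && low < high && high < fs / 2)) {
    stop("band edges must satisfy 0 < low < high < fs/2 (Nyquist)")
  }
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  .filtfilt_pad(bf$b, bf$a, x)
}

#' Integer-factor downsampling
#'
#' Decimates an already low-passed signal by keeping every `fs/target_fs`-th
#' sample (32 kHz to 3.2 kHz for the LFP band by default). The caller is
#' responsible for band-limiting below `target_fs / 2` first; the 4-100 Hz
#' band-pass applied before decimation guarantees the Nyquist margin.
#'
#' @param x numeric signal vector.
#' @param fs original sampling rate, Hz.
#' @param target_fs target rate, Hz; `fs` must be an integer multiple.
#' @return List with elements `x` (decimated signal) and `fs` (`target_fs`).
#' @export
downsample <- function(x, fs, target_fs = 3200) {
  r <- fs / target_fs
  if (abs(r - round(r)) > 1e-9) {
    stop("fs must be an integer multiple of target_fs (got ratio ", r, ")")
  }
  r <- as.integer(round(r))
  list(x = x[seq(1, length(x), by = r)], fs = target_fs)
}

#' Common-average rereferencing
#'
#' Subtracts the across-channel mean at every sample, removing signal shared
#' by all channels (movement artifacts, common volume-conducted components).
#' The channel mean of the output is exactly zero at every time point.
#'
#' @param rec a [recording()] with at least 2 channels (or a channels x time
#'   matrix).
#' @return Object of the same type with rereferenced samples.
#' @export
common_average_rereference <- function(rec) {
  m <- if (inherits(rec, "recording")) rec$samples else rec
  if (nrow(m) < 2) stop("common-average rereferencing requires >= 2 channels")
  out <- sweep(m, 2, colMeans(m))
  if (inherits(rec, "recording")) {
    rec$samples <- out
    rec
  } else {
    out
  }
}

#' Filter a recording into a named analysis band
#'
#' Convenience wrapper applying the pipeline's standard bands per channel:
#' `"lfp"` 4-100 Hz, `"detect"` 1-100 Hz (event detection), `"mua"`
#' 500-5000 Hz; all zero-phase Butterworth of order 3.
#'
#' @param rec a [recording()].
#' @param band `"lfp"`, `"detect"` or `"mua"`.
#' @param order filter order.
#' @return A [recording()] with filtered samples.
#' @export
filter_recording <- function(rec, band = c("lfp", "detect", "mua"), order = 3) {
  band <- match.arg(band)
  edges <- switch(band,
    lfp = c(4, 100), detect = c(1, 100), mua = c(500, 5000))
  rec$samples <- t(apply(rec$samples, 1, bandpass, fs = rec$fs,
                         low = edges[1], high = edges[2], order = order))
  rec
}
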