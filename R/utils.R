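#' @importFrom stats fft rnorm runif rpois rexp sd var quantile median approx
#' @importFrom stats nextn aggregate setNames complete.cases
#' @importFrom rlang .data
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Hann window (periodic form, as used for spectral averaging)
.hann <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n)
}

# Tapered-cosine (Tukey) window; taper = total fraction of the window tapered
.tukey <- function(n, taper = 0.2) {
  if (taper <= 0) return(rep(1, n))
  if (taper >= 1) return(.hann(n))
  t <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  lo <- t < taper / 2
  hi <- t > 1 - taper / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * t[lo] / taper - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * t[hi] / taper - 2 / taper + 1)))
  w
}

#' Welch power spectral density
#'
#' Averaged modified periodogram over non-overlapping Hann-tapered segments.
#' Returned values are one-sided densities, so `sum(psd) * df` approximates
#' the signal variance (Parseval).
#'
#' @param x numeric vector, signal in uV.
#' @param fs sampling rate in Hz.
#' @param seg_len segment length in samples (frequency resolution is
#'   `fs / seg_len` before any zero-padding).
#' @param overlap fractional segment overlap in `[0, 1)` (0 gives the
#'   non-overlapping convention used for event spectra).
#' @param nfft FFT length; segments are zero-padded to `nfft` when it
#'   exceeds `seg_len` (denser frequency grid, unchanged resolution).
#' @param demean subtract the mean of each segment before tapering.
#' @return A tibble with columns `frequency_hz` and `psd` (uV^2/Hz).
#' @export
welch_psd <- function(x, fs, seg_len, overlap = 0, nfft = seg_len,
                      demean = TRUE) {
  stopifnot(is.numeric(x), fs > 0, seg_len >= 2, overlap >= 0, overlap < 1,
            nfft >= seg_len)
  hop <- max(1L, round(seg_len * (1 - overlap)))
  starts <- seq(1L, length(x) - seg_len + 1L, by = hop)
  if (!length(starts)) stop("signal shorter than one segment")
  w <- .hann(seg_len)
  scale <- fs * sum(w^2)
  nf <- floor(nfft / 2) + 1
  pad <- numeric(nfft - seg_len)
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1L)]
    if (demean) seg <- seg - mean(seg)
    sp <- Mod(stats::fft(c(seg * w, pad))[seq_len(nf)])^2 / scale
    acc <- acc + sp
  }
  psd <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist when nfft is even)
  dbl <- rep(2, nf)
  dbl[1] <- 1
  if (nfft %% 2 == 0) dbl[nf] <- 1
  tibble::tibble(
    frequency_hz = (seq_len(nf) - 1) * fs / nfft,
    psd = psd * dbl
  )
}

# Instantaneous phase of the analytic signal (FFT-based Hilbert construction).
# Phase 0 at local maxima of a cosine-like oscillation; range (-pi, pi].
.analytic_phase <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  z <- stats::fft(X * h, inverse = TRUE) / n
  atan2(Im(z), Re(z))
}

# von Mises sampler (Best & Fisher 1979), mean direction mu, concentration kappa
.rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 1e-8) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
      theta <- sign(u[3] - 0.5) * acos(f)
      out[i] <- theta + mu
      i <- i + 1
    }
  }
  atan2(sin(out), cos(out))
}

# wrap angles to (-pi, pi]
.wrap_phase <- function(x) atan2(sin(x), cos(x))

# 1/f^alpha Gaussian noise with unit standard deviation
.pink_noise <- function(n, fs, alpha = 1) {
  nfft <- n
  f <- seq(0, fs / 2, length.out = floor(nfft / 2) + 1)
  amp <- c(0, f[-1]^(-alpha / 2))  # zero DC
  nf <- length(f)
  phases <- stats::runif(nf, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = phases)
  if (nfft %% 2 == 0) {
    full <- c(spec, Conj(rev(spec[2:(nf - 1)])))
  } else {
    full <- c(spec, Conj(rev(spec[2:nf])))
  }
  x <- Re(stats::fft(full, inverse = TRUE))
  x <- x[seq_len(n)]
  x / stats::sd(x)
}

# deterministic child seeds derived from a master seed (kept < 2^31)
.child_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
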