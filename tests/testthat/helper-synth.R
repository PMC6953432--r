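# shared fixtures and oracles, built in code at test time

# rasterized disc of radius r centered in a square matrix
make_circle_mask <- function(r, pad = 10) {
  n <- 2 * r + 2 * pad + 1
  cx <- (n + 1) / 2
  outer(seq_len(n), seq_len(n), function(x, y) (x - cx)^2 + (y - cx)^2 <= r^2)
}

make_square_mask <- function(a, pad = 10) {
  m <- matrix(FALSE, a + 2 * pad, a + 2 * pad)
  m[(pad + 1):(pad + a), (pad + 1):(pad + a)] <- TRUE
  m
}

make_ellipse_mask <- function(a, b, pad = 10) {
  n <- 2 * max(a, b) + 2 * pad + 1
  cx <- (n + 1) / 2
  outer(seq_len(n), seq_len(n),
        function(x, y) ((x - cx) / a)^2 + ((y - cx) / b)^2 <= 1)
}

# rasterized sphere of physical radius r_um on an anisotropic voxel grid
make_sphere_stack <- function(r_um, pixel_size_um, z_step_um, pad_vox = 5) {
  nx <- 2 * ceiling(r_um / pixel_size_um) + 2 * pad_vox + 1
  nz <- 2 * ceiling(r_um / z_step_um) + 2 * pad_vox + 1
  cx <- (nx + 1) / 2
  cz <- (nz + 1) / 2
  arr <- array(FALSE, c(nx, nx, nz))
  for (z in seq_len(nz)) {
    dz2 <- ((z - cz) * z_step_um)^2
    if (dz2 <= r_um^2) {
      arr[, , z] <- outer(seq_len(nx), seq_len(nx), function(x, y) {
        ((x - cx) * pixel_size_um)^2 + ((y - cx) * pixel_size_um)^2 + dz2 <=
          r_um^2
      })
    }
  }
  arr
}

# match detected events against planted truth: an event is recovered when a
# detection overlaps more than half of it; boundary errors from the matched
# detection's onset/offset
match_events <- function(truth, detected) {
  if (nrow(truth) == 0 || nrow(detected) == 0) {
    return(list(sensitivity = 0, precision = 0, boundary_err_s = numeric(0)))
  }
  hits <- 0
  matched_det <- integer(0)
  berr <- numeric(0)
  for (i in seq_len(nrow(truth))) {
    ov <- pmin(detected$stop_s, truth$stop_s[i]) -
      pmax(detected$start_s, truth$start_s[i])
    j <- which.max(ov)
    if (ov[j] > 0.5 * (truth$stop_s[i] - truth$start_s[i])) {
      hits <- hits + 1
      matched_det <- c(matched_det, j)
      berr <- c(berr, abs(detected$start_s[j] - truth$start_s[i]),
                abs(detected$stop_s[j] - truth$stop_s[i]))
    }
  }
  list(sensitivity = hits / nrow(truth),
       precision = length(unique(matched_det)) / nrow(detected),
       boundary_err_s = berr)
}

# a band-limited burst train for constructed-signal detector tests:
# `bursts` is a matrix-like list of c(start, stop) times
make_burst_signal <- function(bursts, duration_s, fs, freq = 20, amp = 10,
                              noise_sd = 1, seed = 1) {
  set.seed(seed)
  n <- round(duration_s * fs)
  x <- rnorm(n, sd = noise_sd)
  for (b in bursts) {
    idx <- (floor(b[1] * fs) + 1):min(n, floor(b[2] * fs))
    tt <- (idx - 1) / fs
    x[idx] <- x[idx] + amp * sin(2 * pi * freq * tt)
  }
  x
}
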