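# rasterize an axis-rotated (xy-plane) ellipsoid into a logical array;
# returns linear voxel indices
.ellipsoid_voxels <- function(dim, center, semi_axes, orientation = 0) {
  a <- semi_axes[1]; b <- semi_axes[2]; c0 <- semi_axes[3]
  r_xy <- max(a, b)
  xs <- max(1, floor(center[1] - r_xy)):min(dim[1], ceiling(center[1] + r_xy))
  ys <- max(1, floor(center[2] - r_xy)):min(dim[2], ceiling(center[2] + r_xy))
  zs <- max(1, floor(center[3] - c0)):min(dim[3], ceiling(center[3] + c0))
  g <- expand.grid(x = xs, y = ys, z = zs)
  dx <- g$x - center[1]; dy <- g$y - center[2]; dz <- g$z - center[3]
  xr <- dx * cos(orientation) + dy * sin(orientation)
  yr <- -dx * sin(orientation) + dy * cos(orientation)
  inside <- (xr / a)^2 + (yr / b)^2 + (dz / c0)^2 <= 1
  (g$x[inside]) + (g$y[inside] - 1) * dim[1] + (g$z[inside] - 1) * dim[1] * dim[2]
}

.sphere_voxels <- function(dim, center, r) {
  .ellipsoid_voxels(dim, center, c(r, r, r), 0)
}

# greedy sampling of k points with pairwise min distance from a candidate
# set; randomized greedy packing can stall below the true packing number,
# so several independent orders are tried
.pick_spaced <- function(cand, k, min_dist, tries = 50) {
  for (t in seq_len(tries)) {
    picked <- matrix(numeric(0), 0, 3)
    ord <- sample(nrow(cand))
    for (i in ord) {
      p <- cand[i, , drop = FALSE]
      if (nrow(picked) == 0 ||
          all(sqrt(rowSums(sweep(picked, 2, as.numeric(p))^2)) >= min_dist)) {
        picked <- rbind(picked, p)
        if (nrow(picked) == k) return(picked)
      }
    }
  }
  NULL
}

#' Generate a synthetic microglia / VGLUT1 two-channel image stack
#'
#' Builds a 3D fixture with exactly known ground truth: ellipsoidal
#' microglia somata (bright core, dim halo) placed on a jittered grid so
#' that no cell touches another cell's 110x110 region of interest or the
#' image border, plus spherical VGLUT1-like puncta either fully embedded in
#' a cell (with a 2-voxel containment margin) or in the background away from
#' all cells. Both channels carry weak Gaussian noise over a low uniform
#' background. Cell processes are not emulated (`branch_count` is 0).
#'
#' @param n_cells number of cells.
#' @param n_puncta_inside puncta fully contained in cells (assigned
#'   round-robin).
#' @param n_puncta_outside background puncta.
#' @param dim image dimensions `c(nx, ny, nz)` in voxels.
#' @param cell_semi_axes_px ellipsoid semi-axes `c(a, b, c)` in voxels.
#' @param punctum_radius_px punctum radius in voxels (default gives
#'   rasterized volumes of ~140 voxels, inside the 100-500 gate).
#' @param pixel_size_um,z_step_um spatial calibration (defaults 0.103 and
#'   0.75 um, the high-magnification engulfment-imaging settings).
#' @param seed integer seed.
#' @return List with `iba` and `vglut` (numeric 3D arrays in `[0, 1]`),
#'   `truth` (list of `cells` and `puncta` tibbles), and the calibration.
#' @export
gen_microglia_stack <- function(n_cells = 7, n_puncta_inside = 12,
                                n_puncta_outside = 5, dim = c(512, 512, 24),
                                cell_semi_axes_px = c(18, 12, 5),
                                punctum_radius_px = 3.2,
                                pixel_size_um = 0.103, z_step_um = 0.75,
                                seed = 1) {
  set.seed(seed)
  a <- cell_semi_axes_px[1]; b <- cell_semi_axes_px[2]; cc <- cell_semi_axes_px[3]
  stopifnot(a >= b, cc + 3 <= dim[3] / 2)
  roi_half <- 55
  spacing <- 2 * roi_half + 10
  margin <- roi_half + 5
  gx <- seq(margin, dim[1] - margin, by = spacing)
  gy <- seq(margin, dim[2] - margin, by = spacing)
  if (length(gx) * length(gy) < n_cells) {
    stop("requested geometry not placeable: ", n_cells,
         " cells do not fit a ", dim[1], "x", dim[2],
         " image with non-overlapping 110x110 ROIs")
  }
  slots <- expand.grid(x = gx, y = gy)
  slots <- slots[sample(nrow(slots), n_cells), , drop = FALSE]
  zc <- dim[3] / 2
  cells <- tibble::tibble(
    cell = seq_len(n_cells),
    x = slots$x + stats::runif(n_cells, -8, 8),
    y = slots$y + stats::runif(n_cells, -8, 8),
    z = zc + stats::runif(n_cells, -1, 1),
    a = a, b = b, c = cc,
    orientation_rad = stats::runif(n_cells, 0, pi),
    branch_count = 0L)

  iba <- array(pmax(0, 0.03 + stats::rnorm(prod(dim), 0, 0.015)), dim)
  vglut <- array(pmax(0, 0.02 + stats::rnorm(prod(dim), 0, 0.01)), dim)

  core_idx <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    ctr <- c(cells$x[i], cells$y[i], cells$z[i])
    halo <- .ellipsoid_voxels(dim, ctr, c(a + 2, b + 2, cc + 2),
                              cells$orientation_rad[i])
    core <- .ellipsoid_voxels(dim, ctr, c(a, b, cc), cells$orientation_rad[i])
    iba[halo] <- 0.3
    iba[core] <- 1
    core_idx[[i]] <- core
  }

  pr <- punctum_radius_px
  min_sep <- 2 * pr + 7  # keeps puncta separable through the max filter
  puncta <- tibble::tibble(id = integer(0), x = numeric(0), y = numeric(0),
                           z = numeric(0), radius_px = numeric(0),
                           volume_px = integer(0), inside_cell = integer(0))
  pid <- 0L
  if (n_puncta_inside > 0) {
    per_cell <- tabulate(rep(seq_len(n_cells), length.out = n_puncta_inside),
                         n_cells)
    for (i in seq_len(n_cells)) {
      if (per_cell[i] == 0) next
      m <- pr + 2  # containment margin after rasterization
      th <- cells$orientation_rad[i]
      gg <- expand.grid(
        u = seq(-(a - m), a - m, by = 2), v = seq(-(b - m), b - m, by = 2),
        w = seq(-(cc - m), cc - m, by = 1))
      gg <- gg[(gg$u / (a - m))^2 + (gg$v / (b - m))^2 + (gg$w / (cc - m))^2 <= 1, ]
      if (nrow(gg) == 0) {
        stop("requested geometry not placeable: cell too small to embed puncta")
      }
      cand <- cbind(cells$x[i] + gg$u * cos(th) - gg$v * sin(th),
                    cells$y[i] + gg$u * sin(th) + gg$v * cos(th),
                    cells$z[i] + gg$w)
      pk <- .pick_spaced(cand, per_cell[i], min_sep)
      if (is.null(pk)) {
        stop("requested geometry not placeable: cannot embed ", per_cell[i],
             " puncta in one cell with ", min_sep, "-px separation")
      }
      for (j in seq_len(nrow(pk))) {
        pid <- pid + 1L
        vox <- .sphere_voxels(dim, pk[j, ], pr)
        vglut[vox] <- 1
        puncta <- dplyr::bind_rows(puncta, tibble::tibble(
          id = pid, x = pk[j, 1], y = pk[j, 2], z = pk[j, 3],
          radius_px = pr, volume_px = length(vox), inside_cell = i))
      }
    }
  }
  if (n_puncta_outside > 0) {
    bmar <- ceiling(pr) + 3
    cand <- cbind(stats::runif(600, bmar, dim[1] - bmar),
                  stats::runif(600, bmar, dim[2] - bmar),
                  stats::runif(600, bmar, dim[3] - bmar))
    far <- apply(cand, 1, function(p) {
      all(sqrt((p[1] - cells$x)^2 + (p[2] - cells$y)^2) > a + pr + 12)
    })
    pk <- .pick_spaced(cand[far, , drop = FALSE], n_puncta_outside, min_sep)
    if (is.null(pk)) stop("requested geometry not placeable: too many background puncta")
    for (j in seq_len(nrow(pk))) {
      pid <- pid + 1L
      vox <- .sphere_voxels(dim, pk[j, ], pr)
      vglut[vox] <- 1
      puncta <- dplyr::bind_rows(puncta, tibble::tibble(
        id = pid, x = pk[j, 1], y = pk[j, 2], z = pk[j, 3],
        radius_px = pr, volume_px = length(vox), inside_cell = NA_integer_))
    }
  }
  list(iba = iba, vglut = vglut,
       truth = list(cells = cells, puncta = puncta),
       pixel_size_um = pixel_size_um, z_step_um = z_step_um)
}
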