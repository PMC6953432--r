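# maximum-intensity z-projection
.max_project <- function(stack) {
  if (length(dim(stack)) == 2) return(stack)
  Reduce(pmax, lapply(seq_len(dim(stack)[3]), function(z) stack[, , z]))
}

# triangle-method automatic threshold on a 256-bin histogram; invariant to
# affine intensity rescaling because the histogram spans [min, max]
.triangle_threshold <- function(v, n_bins = 256) {
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1] + 1)  # flat image: nothing above
  h <- graphics::hist(v, breaks = seq(rng[1], rng[2], length.out = n_bins + 1),
                      plot = FALSE)
  counts <- h$counts
  peak <- which.max(counts)
  nz <- which(counts > 0)
  # tail = the longer side from the peak
  if ((max(nz) - peak) >= (peak - min(nz))) {
    idx <- peak:max(nz)
  } else {
    idx <- peak:min(nz)
  }
  x1 <- idx[1]; y1 <- counts[x1]
  x2 <- idx[length(idx)]; y2 <- counts[x2]
  d <- abs((y2 - y1) * idx - (x2 - x1) * counts[idx] + x2 * y1 - y2 * x1) /
    sqrt((y2 - y1)^2 + (x2 - x1)^2)
  h$mids[idx[which.max(d)]]
}

# Otsu's threshold (between-class variance maximization) on 256 bins
.otsu_threshold <- function(v, n_bins = 256) {
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1] + 1)
  h <- graphics::hist(v, breaks = seq(rng[1], rng[2], length.out = n_bins + 1),
                      plot = FALSE)
  w <- h$counts / sum(h$counts)
  mu <- h$mids
  omega <- cumsum(w)
  mu_k <- cumsum(w * mu)
  mu_t <- mu_k[length(mu_k)]
  sigma_b <- (mu_t * omega - mu_k)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  h$mids[which.max(sigma_b)]
}

.disc_brush <- function(radius) EBImage::makeBrush(2 * radius + 1, "disc")

#' Count labeled cells in an image stack
#'
#' Maximum-intensity z-projection, despeckle (3x3 median), Gaussian smoothing
#' (sigma = 2), triangle-method automatic binarization, and connected-
#' component counting with a strict size gate (> 150 px by default).
#'
#' @param stack 2D matrix or 3D array of intensities.
#' @param min_size_px strict lower size bound in pixels.
#' @param pixel_size_um pixel size for the density denominator, um.
#' @param sigma Gaussian blur SD in pixels.
#' @return One-row tibble: `count` and `density_per_mm2`.
#' @export
count_cells <- function(stack, min_size_px = 150, pixel_size_um = 0.732,
                        sigma = 2) {
  proj <- .max_project(stack)
  if (diff(range(proj)) == 0) {
    area_mm2 <- prod(dim(proj)) * (pixel_size_um / 1000)^2
    return(tibble::tibble(count = 0L, density_per_mm2 = 0))
  }
  proj <- (proj - min(proj)) / diff(range(proj))
  proj <- EBImage::medianFilter(proj, size = 1)
  proj <- EBImage::gblur(proj, sigma = sigma)
  thr <- .triangle_threshold(as.numeric(proj))
  lab <- EBImage::bwlabel(proj > thr)
  sizes <- tabulate(as.integer(lab))
  count <- sum(sizes > min_size_px)
  area_mm2 <- prod(dim(proj)) * (pixel_size_um / 1000)^2
  tibble::tibble(count = as.integer(count), density_per_mm2 = count / area_mm2)
}

#' Segment putative microglia from a 2D projection
#'
#' Global automatic threshold (Otsu), connected components inside the
#' 200-1500 px size gate, and a 110x110 region of interest around each
#' centroid; cells whose mask touches the ROI border, whose ROI leaves the
#' image, or whose ROI contains pixels of another component are discarded
#' (the automated counterpart of the visual-exclusion rule).
#'
#' @param projection 2D intensity matrix (max projection).
#' @param area_range inclusive size gate in pixels.
#' @param roi_size ROI side length in pixels.
#' @return Tibble with `cell`, centroid `x`/`y`, `area_px` and a `mask`
#'   list-column of ROI-cropped logical matrices.
#' @export
segment_cells_2d <- function(projection, area_range = c(200, 1500),
                             roi_size = 110) {
  thr <- .otsu_threshold(as.numeric(projection))
  lab <- EBImage::bwlabel(projection > thr)
  labm <- as.matrix(lab)
  sizes <- tabulate(as.integer(labm))
  keep_ids <- which(sizes >= area_range[1] & sizes <= area_range[2])
  half <- floor(roi_size / 2)
  out <- tibble::tibble(cell = integer(0), x = numeric(0), y = numeric(0),
                        area_px = integer(0), mask = list())
  k <- 0L
  for (id in keep_ids) {
    pix <- which(labm == id, arr.ind = TRUE)
    cx <- round(mean(pix[, 1])); cy <- round(mean(pix[, 2]))
    x0 <- cx - half; x1 <- cx + half
    y0 <- cy - half; y1 <- cy + half
    if (x0 < 1 || y0 < 1 || x1 > nrow(labm) || y1 > ncol(labm)) next
    roi <- labm[x0:x1, y0:y1]
    # discard if the cell touches the ROI border or shares the ROI
    border <- c(roi[1, ], roi[nrow(roi), ], roi[, 1], roi[, ncol(roi)])
    if (any(border == id)) next
    if (any(roi != 0 & roi != id)) next
    k <- k + 1L
    out <- dplyr::bind_rows(out, tibble::tibble(
      cell = k, x = mean(pix[, 1]), y = mean(pix[, 2]),
      area_px = sizes[id], mask = list(roi == id)))
  }
  out
}

# chain-code perimeter with the Vossepoel-Smeulders correction:
# 0.980 * (axial steps) + 1.406 * (diagonal steps) - 0.091 * (corners)
.chain_perimeter <- function(mask) {
  ct <- EBImage::ocontour(EBImage::Image(mask * 1))
  if (!length(ct)) stop("no contour found")
  per <- 0
  for (cc in ct) {
    pts <- rbind(cc, cc[1, , drop = FALSE])
    d <- diff(pts)
    diag_step <- rowSums(abs(d)) == 2
    ne <- sum(!diag_step)
    no <- sum(diag_step)
    code <- atan2(d[, 2], d[, 1])
    nc <- sum(abs(diff(c(code, code[1]))) > 1e-9)
    per <- per + 0.980 * ne + 1.406 * no - 0.091 * nc
  }
  per
}

# MATLAB-style 8 extremal boundary points of a 2D mask
.extrema_points <- function(mask) {
  pix <- which(mask, arr.ind = TRUE)
  x <- pix[, 1]; y <- pix[, 2]
  rbind(
    c(min(x[y == min(y)]), min(y)),  # top-left
    c(max(x[y == min(y)]), min(y)),  # top-right
    c(max(x), min(y[x == max(x)])),  # right-top
    c(max(x), max(y[x == max(x)])),  # right-bottom
    c(max(x[y == max(y)]), max(y)),  # bottom-right
    c(min(x[y == max(y)]), max(y)),  # bottom-left
    c(min(x), max(y[x == min(x)])),  # left-bottom
    c(min(x), min(y[x == min(x)]))   # left-top
  )
}

#' Morphometric features of a segmented cell
#'
#' Area and corrected chain-code perimeter; eccentricity of the
#' equivalent-ellipse second moments; cell spread (a proxy for process
#' length) as the mean distance between the center of mass and the 8
#' extremal boundary points; roundness as `4 * pi * area / perimeter^2`
#' (1 for a disc, `pi/4` for a square in the large-size limit).
#'
#' @param mask logical 2D matrix (one connected cell).
#' @param pixel_size_um optional pixel size; when given, `area_um2`,
#'   `perimeter_um` and `spread_um` are appended.
#' @return One-row tibble: `area_px`, `perimeter_px`, `eccentricity`,
#'   `spread_px`, `roundness` (plus calibrated columns when requested).
#' @export
cell_features <- function(mask, pixel_size_um = NULL) {
  stopifnot(is.matrix(mask))
  mask <- mask != 0
  area <- sum(mask)
  if (area < 5) stop("degenerate mask: too few pixels for shape features")
  pix <- which(mask, arr.ind = TRUE)
  ctr <- colMeans(pix)
  cen <- sweep(pix, 2, ctr)
  cv <- crossprod(cen) / area
  ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  ecc <- sqrt(max(0, 1 - ev[2] / ev[1]))
  per <- .chain_perimeter(mask)
  ex <- .extrema_points(mask)
  spread <- mean(sqrt((ex[, 1] - ctr[1])^2 + (ex[, 2] - ctr[2])^2))
  out <- tibble::tibble(
    area_px = area, perimeter_px = per, eccentricity = ecc,
    spread_px = spread, roundness = 4 * pi * area / per^2)
  if (!is.null(pixel_size_um)) {
    out$area_um2 <- area * pixel_size_um^2
    out$perimeter_um <- per * pixel_size_um
    out$spread_um <- spread * pixel_size_um
  }
  out
}

# 26-connected dilation of a logical 3D array by one voxel
.dilate26 <- function(m) {
  d <- dim(m)
  out <- m
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    xs <- max(1, 1 + dx):min(d[1], d[1] + dx)
    ys <- max(1, 1 + dy):min(d[2], d[2] + dy)
    zs <- max(1, 1 + dz):min(d[3], d[3] + dz)
    out[xs, ys, zs] <- out[xs, ys, zs] | m[xs - dx, ys - dy, zs - dz]
  }
  out
}

# 3x3x3 majority (binary median) filter via neighborhood sums
.median3d_binary <- function(m) {
  d <- dim(m)
  acc <- array(0, d)
  num <- array(0, d)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    xs <- max(1, 1 + dx):min(d[1], d[1] + dx)
    ys <- max(1, 1 + dy):min(d[2], d[2] + dy)
    zs <- max(1, 1 + dz):min(d[3], d[3] + dz)
    acc[xs, ys, zs] <- acc[xs, ys, zs] + m[xs - dx, ys - dy, zs - dz]
    num[xs, ys, zs] <- num[xs, ys, zs] + 1
  }
  acc > num / 2
}

#' 3D hysteresis segmentation
#'
#' Voxels at or above the `high` fraction of the intensity range seed the
#' segmentation; voxels at or above the `low` fraction are kept if and only
#' if they are 26-connected to a seed. A 3x3x3 median (majority) filter
#' smooths the resulting binary stack.
#'
#' @param stack numeric 3D array.
#' @param low,high thresholds as fractions of the intensity range,
#'   `0 <= low < high <= 1`.
#' @param connectivity neighborhood (26 is the only implemented option).
#' @param median_filter apply the 3x3x3 median smoothing.
#' @return Logical 3D array.
#' @export
hysteresis_3d <- function(stack, low = 0.1, high = 0.5, connectivity = 26,
                          median_filter = TRUE) {
  if (low >= high) stop("low threshold must be strictly below high")
  stopifnot(low >= 0, high <= 1, connectivity == 26)
  rng <- range(stack)
  if (diff(rng) == 0) return(array(FALSE, dim(stack)))
  lo <- rng[1] + low * diff(rng)
  hi <- rng[1] + high * diff(rng)
  mask <- stack >= lo
  cur <- stack >= hi
  if (!any(cur)) return(array(FALSE, dim(stack)))
  repeat {
    nxt <- .dilate26(cur) & mask
    if (sum(nxt) == sum(cur)) break
    cur <- nxt
  }
  if (median_filter) cur <- .median3d_binary(cur)
  cur
}

# union-find
.uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

# 3D labeling from per-slice 2D label planes. across = "dilate" links
# slice-adjacent components through the full 26-neighborhood; "overlap"
# links only directly superimposed voxels (used after watershed splitting so
# in-plane splits are not re-merged through diagonal contact).
.label3d <- function(planes, across = c("dilate", "overlap")) {
  across <- match.arg(across)
  nz <- length(planes)
  offs <- c(0, cumsum(vapply(planes, max, numeric(1))))[seq_len(nz)]
  planes <- mapply(function(p, o) {
    p[p > 0] <- p[p > 0] + o
    p
  }, planes, offs, SIMPLIFY = FALSE)
  total <- max(vapply(planes, max, numeric(1)))
  if (total == 0) {
    return(array(0L, c(dim(planes[[1]]), nz)))
  }
  parent <- seq_len(total)
  link <- function(a, b) {
    ra <- .uf_find(parent, a); rb <- .uf_find(parent, b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  kern <- EBImage::makeBrush(3, "box")
  for (z in seq_len(nz - 1)) {
    p1 <- planes[[z]]; p2 <- planes[[z + 1]]
    ov <- p1 > 0 & p2 > 0
    if (any(ov)) {
      pairs <- unique(cbind(p1[ov], p2[ov]))
      for (r in seq_len(nrow(pairs))) link(pairs[r, 1], pairs[r, 2])
    }
    if (across == "dilate") {
      d1 <- as.matrix(EBImage::dilate(p1, kern))  # grayscale max-dilation
      ov <- d1 > 0 & p2 > 0
      if (any(ov)) {
        pairs <- unique(cbind(d1[ov], p2[ov]))
        for (r in seq_len(nrow(pairs))) link(pairs[r, 1], pairs[r, 2])
      }
      d2 <- as.matrix(EBImage::dilate(p2, kern))
      ov <- p1 > 0 & d2 > 0
      if (any(ov)) {
        pairs <- unique(cbind(p1[ov], d2[ov]))
        for (r in seq_len(nrow(pairs))) link(pairs[r, 1], pairs[r, 2])
      }
    }
  }
  roots <- vapply(seq_len(total), function(i) .uf_find(parent, i), numeric(1))
  relab <- match(roots, sort(unique(roots)))
  arr <- array(0L, c(dim(planes[[1]]), nz))
  for (z in seq_len(nz)) {
    p <- planes[[z]]
    nzv <- p > 0
    p[nzv] <- relab[p[nzv]]
    arr[, , z] <- p
  }
  arr
}

#' Detect VGLUT1-like puncta in a 3D stack
#'
#' Rolling-ball background subtraction (grayscale tophat; the effective
#' footprint is four times the nominal ball radius, mirroring the original
#' rolling-ball implementation whose contact patch spans several times the
#' nominal radius), despeckle (3x3 median per plane), maximum filter
#' (2-px disc per plane), automatic Otsu binarization, erosion by the same
#' 2-px element (so that maximum filter + threshold + erosion acts as a
#' morphological closing and measured volumes refer to the native punctum
#' scale), per-plane watershed splitting of touching puncta, 3D labeling
#' (8-connectivity in plane, direct overlap across planes) and a 100-500
#' voxel size gate.
#'
#' @param stack numeric 3D array (single channel).
#' @param background_radius nominal rolling-ball radius, px (`NULL` skips).
#' @param max_radius maximum-filter radius, px.
#' @param size_range inclusive volume gate in voxels.
#' @return List with `labels` (integer 3D array, gated puncta labeled
#'   `1..K`) and `table` (tibble: `id`, `volume_px`, centroid `x`/`y`/`z`).
#' @export
detect_puncta <- function(stack, background_radius = 2, max_radius = 2,
                          size_range = c(100, 500)) {
  stopifnot(length(dim(stack)) == 3)
  nz <- dim(stack)[3]
  x <- stack
  if (!is.null(background_radius)) {
    kern_bg <- .disc_brush(4 * background_radius)
    for (z in seq_len(nz)) {
      bg <- as.matrix(EBImage::opening(x[, , z], kern_bg))
      x[, , z] <- pmax(x[, , z] - bg, 0)
    }
  }
  mx <- max(x)
  if (mx == 0) {
    return(list(labels = array(0L, dim(stack)),
                table = tibble::tibble(id = integer(0), volume_px = integer(0),
                                       x = numeric(0), y = numeric(0),
                                       z = numeric(0))))
  }
  x <- x / mx
  kern_max <- .disc_brush(max_radius)
  for (z in seq_len(nz)) {
    sl <- EBImage::medianFilter(x[, , z], size = 1)
    x[, , z] <- as.matrix(EBImage::dilate(sl, kern_max))
  }
  thr <- .otsu_threshold(as.numeric(x))
  planes <- vector("list", nz)
  for (z in seq_len(nz)) {
    b <- x[, , z] > thr
    b <- as.matrix(EBImage::erode(b, kern_max)) > 0
    if (any(b)) {
      dm <- EBImage::distmap(b)
      planes[[z]] <- as.matrix(EBImage::watershed(dm))
    } else {
      planes[[z]] <- matrix(0L, dim(stack)[1], dim(stack)[2])
    }
  }
  labs <- .label3d(planes, across = "overlap")
  vols <- tabulate(labs[labs > 0])
  keep <- which(vols >= size_range[1] & vols <= size_range[2])
  relab <- integer(length(vols))
  relab[keep] <- seq_along(keep)
  out <- labs
  nzv <- out > 0
  out[nzv] <- relab[out[nzv]]
  tab <- purrr::map_dfr(seq_along(keep), function(i) {
    vox <- which(out == i, arr.ind = TRUE)
    tibble::tibble(id = i, volume_px = nrow(vox), x = mean(vox[, 1]),
                   y = mean(vox[, 2]), z = mean(vox[, 3]))
  })
  if (nrow(tab) == 0) {
    tab <- tibble::tibble(id = integer(0), volume_px = integer(0),
                          x = numeric(0), y = numeric(0), z = numeric(0))
  }
  list(labels = out, table = tab)
}

#' Engulfed-puncta metrics for one microglial cell
#'
#' A punctum counts as phagocytosed only under 100% xyz overlap: every one
#' of its voxels must lie inside the processed cell mask.
#'
#' @param cell logical 3D cell mask (e.g. from [hysteresis_3d()]).
#' @param puncta [detect_puncta()] output (or an integer label array).
#' @param pixel_size_um,z_step_um calibration for the volume in um^3.
#' @return One-row tibble: `count`, `total_volume_px`, `total_volume_um3`.
#' @export
engulfment_metrics <- function(cell, puncta, pixel_size_um = 0.103,
                               z_step_um = 0.75) {
  labs <- if (is.list(puncta)) puncta$labels else puncta
  if (!all(dim(cell) == dim(labs))) {
    stop("cell mask and puncta stack have different shapes")
  }
  n_lab <- max(labs)
  if (n_lab == 0) {
    return(tibble::tibble(count = 0L, total_volume_px = 0L,
                          total_volume_um3 = 0))
  }
  all_vol <- tabulate(labs[labs > 0], n_lab)
  inside_vol <- tabulate(labs[labs > 0 & cell], n_lab)
  engulfed <- which(all_vol > 0 & inside_vol == all_vol)
  tot <- sum(all_vol[engulfed])
  tibble::tibble(count = length(engulfed), total_volume_px = as.integer(tot),
                 total_volume_um3 = tot * pixel_size_um^2 * z_step_um)
}

#' Distal cell volume
#'
#' Volume of mask voxels farther than `radius_um` (default 7 um) from the
#' cell's center of mass, with anisotropy-corrected physical distances
#' (lateral pixel and z-step differ by an order of magnitude at the default
#' calibration).
#'
#' @param cell logical 3D cell mask.
#' @param radius_um cutoff distance from the center of mass, um.
#' @param pixel_size_um,z_step_um calibration (must be supplied; defaults are
#'   the engulfment-imaging settings 0.103 and 0.75 um).
#' @return Distal volume in um^3.
#' @export
distal_volume <- function(cell, radius_um = 7, pixel_size_um = 0.103,
                          z_step_um = 0.75) {
  if (is.null(pixel_size_um) || is.null(z_step_um) ||
      is.na(pixel_size_um) || is.na(z_step_um)) {
    stop("spatial calibration (pixel_size_um, z_step_um) is required")
  }
  vox <- which(cell, arr.ind = TRUE)
  if (nrow(vox) == 0) return(0)
  phys <- cbind(vox[, 1] * pixel_size_um, vox[, 2] * pixel_size_um,
                vox[, 3] * z_step_um)
  ctr <- colMeans(phys)
  d <- sqrt((phys[, 1] - ctr[1])^2 + (phys[, 2] - ctr[2])^2 +
              (phys[, 3] - ctr[3])^2)
  sum(d >= radius_um) * pixel_size_um^2 * z_step_um
}
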