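test_that("cell counting recovers planted cells and applies the size gate", {
  g <- gen_microglia_stack(n_cells = 7, n_puncta_inside = 0,
                           n_puncta_outside = 0, dim = c(512, 512, 16),
                           seed = 34)
  cc <- count_cells(g$iba)
  expect_equal(cc$count, 7)
  # invariant to global intensity rescaling (triangle threshold)
  expect_equal(count_cells(g$iba * 2)$count, 7)
  # a small speckle-scale blob fails the > 150 px gate (the gate applies to
  # the blurred, thresholded component, which is larger than the native blob)
  set.seed(46)
  img <- matrix(pmax(0, rnorm(200 * 200, 0.05, 0.02)), 200, 200)
  blob <- make_circle_mask(3, pad = 0)
  img[30 + seq_len(nrow(blob)), 30 + seq_len(ncol(blob))][blob] <- 1
  expect_equal(count_cells(img)$count, 0)
  big <- make_circle_mask(15, pad = 0)
  img[120 + seq_len(nrow(big)), 120 + seq_len(ncol(big))][big] <- 1
  expect_equal(count_cells(img)$count, 1)
  # flat image: zero cells, no error
  expect_equal(count_cells(matrix(0.5, 64, 64))$count, 0)
})

test_that("2D segmentation applies size gates and ROI exclusion rules", {
  img <- matrix(0.02, 400, 400)
  put <- function(img, mask, x0, y0) {
    img[x0 + seq_len(nrow(mask)), y0 + seq_len(ncol(mask))][mask] <- 1
    img
  }
  # isolated 600-px blob -> kept
  img <- put(img, make_circle_mask(14, pad = 0), 100, 100)
  # 1800-px blob -> excluded by the upper gate
  img <- put(img, make_circle_mask(24, pad = 0), 280, 100)
  # two small blobs 20 px apart -> both excluded (shared ROI)
  img <- put(img, make_circle_mask(9, pad = 0), 100, 280)
  img <- put(img, make_circle_mask(9, pad = 0), 140, 280)
  seg <- segment_cells_2d(img)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$area_px, sum(make_circle_mask(14, pad = 0)))
  # a cell near the image border (ROI leaves the image) is dropped
  img2 <- put(matrix(0.02, 400, 400), make_circle_mask(14, pad = 0), 5, 180)
  expect_equal(nrow(segment_cells_2d(img2)), 0)
})

test_that("shape features match analytic values for rasterized primitives", {
  circ <- cell_features(make_circle_mask(40))
  expect_lt(abs(circ$area_px - pi * 1600) / (pi * 1600), 0.02)
  expect_gte(circ$roundness, 0.95)
  expect_lte(circ$eccentricity, 0.2)
  expect_equal(circ$spread_px, 40, tolerance = 0.05)
  # large square: roundness -> pi/4, spread -> mean of side/2 and diagonal/2
  sq <- cell_features(make_square_mask(200))
  expect_lt(abs(sq$roundness - pi / 4), 0.05)
  expect_lt(sq$eccentricity, 0.05)
  # 4:1 ellipse: eccentricity sqrt(1 - 1/16)
  ell <- cell_features(make_ellipse_mask(120, 30))
  expect_equal(ell$eccentricity, sqrt(1 - 1 / 16), tolerance = 0.02)
  # calibration appends physical units
  f <- cell_features(make_circle_mask(20), pixel_size_um = 0.5)
  expect_equal(f$area_um2, f$area_px * 0.25)
  expect_error(cell_features(matrix(c(TRUE, rep(FALSE, 8)), 3, 3)),
               "degenerate")
})

test_that("hysteresis keeps low-intensity halos only when seeded", {
  dim3 <- c(60, 60, 12)
  stack <- array(0, dim3)
  # blob with bright core and dim halo -> retained entirely
  core <- neonosc:::.ellipsoid_voxels(dim3, c(20, 20, 6), c(6, 6, 3))
  halo <- neonosc:::.ellipsoid_voxels(dim3, c(20, 20, 6), c(9, 9, 5))
  stack[halo] <- 0.3
  stack[core] <- 0.8
  # isolated dim voxels with no seed -> removed
  iso <- neonosc:::.ellipsoid_voxels(dim3, c(45, 45, 6), c(4, 4, 2))
  stack[iso] <- 0.3
  # make the intensity range span [0, 1] so fractions are absolute
  stack[1, 1, 1] <- 1
  out <- hysteresis_3d(stack, 0.1, 0.5, median_filter = FALSE)
  expect_true(all(out[halo]))
  expect_true(!any(out[iso]))
  expect_false(any(hysteresis_3d(array(0, dim3), 0.1, 0.5)))
  expect_error(hysteresis_3d(stack, 0.6, 0.5), "below high")
})

test_that("puncta detection gates sizes and splits touching puncta", {
  dim3 <- c(100, 100, 20)
  stack <- array(0.02, dim3)
  add_sphere <- function(stack, ctr, r, val = 1) {
    stack[neonosc:::.sphere_voxels(dim3, ctr, r)] <- val
    stack
  }
  stack <- add_sphere(stack, c(25, 25, 10), 3.6)   # ~180 px, kept
  stack <- add_sphere(stack, c(70, 25, 10), 2.2)   # ~45 px, discarded
  stack <- add_sphere(stack, c(25, 70, 10), 5.6)   # ~740 px, discarded
  pd <- detect_puncta(stack)
  expect_equal(nrow(pd$table), 1)
  planted_vol <- length(neonosc:::.sphere_voxels(dim3, c(25, 25, 10), 3.6))
  expect_lt(abs(pd$table$volume_px - planted_vol) / planted_vol, 0.15)
  expect_equal(pd$table$x, 25, tolerance = 1)
  # two touching puncta are separated by the watershed
  stack2 <- array(0.02, dim3)
  stack2 <- add_sphere(stack2, c(40, 50, 10), 3.6)
  stack2 <- add_sphere(stack2, c(49, 50, 10), 3.6)
  pd2 <- detect_puncta(stack2)
  expect_equal(nrow(pd2$table), 2)
})

test_that("engulfment requires 100% voxel overlap", {
  dim3 <- c(80, 80, 16)
  cell <- array(FALSE, dim3)
  cell[neonosc:::.ellipsoid_voxels(dim3, c(40, 40, 8), c(25, 25, 6))] <- TRUE
  labs <- array(0L, dim3)
  labs[neonosc:::.sphere_voxels(dim3, c(40, 40, 8), 3)] <- 1L   # inside
  labs[neonosc:::.sphere_voxels(dim3, c(10, 10, 8), 3)] <- 2L   # outside
  # punctum 3 fully inside except one voxel
  vox3 <- neonosc:::.sphere_voxels(dim3, c(50, 40, 8), 3)
  labs[vox3] <- 3L
  labs[10, 10, 1] <- 3L
  em <- engulfment_metrics(cell, labs)
  expect_equal(em$count, 1)
  expect_equal(em$total_volume_px,
               length(neonosc:::.sphere_voxels(dim3, c(40, 40, 8), 3)))
  expect_error(engulfment_metrics(cell[1:40, , ], labs), "different shapes")
})

test_that("planted engulfment counts are recovered exactly", {
  g <- gen_microglia_stack(n_cells = 1, n_puncta_inside = 6,
                           n_puncta_outside = 3, dim = c(160, 160, 24),
                           cell_semi_axes_px = c(38, 28, 8), seed = 35)
  cell <- hysteresis_3d(g$iba)
  pd <- detect_puncta(g$vglut)
  expect_equal(nrow(pd$table), 9)
  em <- engulfment_metrics(cell, pd)
  expect_equal(em$count, 6)
})

test_that("distal volume matches the analytic spherical shell", {
  px <- 0.103; zs <- 0.75
  sph10 <- make_sphere_stack(10, px, zs)
  dv <- distal_volume(sph10, 7, px, zs)
  shell <- 4 / 3 * pi * (10^3 - 7^3)
  expect_lt(abs(dv - shell) / shell, 0.05)
  # a 5-um sphere lies entirely within the 7-um cutoff
  expect_equal(distal_volume(make_sphere_stack(5, px, zs), 7, px, zs), 0)
  # zero cutoff returns the total volume
  expect_equal(distal_volume(sph10, 0, px, zs),
               sum(sph10) * px^2 * zs)
  expect_error(distal_volume(sph10, 7, NA, zs), "calibration")
})
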