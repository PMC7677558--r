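test_that("fusion is the weighted voxelwise sum with printed defaults", {
  z <- array(0, c(4, 4, 2))
  expect_true(all(fuse_images(z, z, z) == 0))
  one <- array(1, c(2, 2))
  ## alpha 1000 + beta 100 + gamma 6 on unit inputs
  expect_equal(fuse_images(one, one, one)[1, 1], 1106)
  ## weight (1,0,0) projects the SOS volume
  sos <- matrix(rnorm(16), 4)
  expect_equal(fuse_images(sos, 0 * sos, 0 * sos, 1, 0, 0), sos)
  ## exact linearity in the inputs
  a <- matrix(runif(16), 4); b <- matrix(runif(16), 4)
  r <- matrix(runif(16), 4)
  expect_equal(fuse_images(3 * a, 3 * b, 3 * r), 3 * fuse_images(a, b, r),
               tolerance = 1e-12)
  expect_error(fuse_images(a, b, matrix(0, 3, 3)), "grid")
  expect_error(fuse_images(a, b, r, 0, 0, 0), "nonzero")
  inv <- fuse_images(a, b, r, invert_grayscale = TRUE)
  expect_equal(max(fuse_images(a, b, r)) - fuse_images(a, b, r), inv)
})

test_that("opening removes sub-element speckle and is idempotent", {
  ## brute-force oracle on a 9^3 toy volume: erosion keeps voxels whose
  ## whole ball fits, dilation marks every touched voxel
  set.seed(8)
  m <- array(runif(9^3) > 0.7, c(9, 9, 9))
  offs <- paraxtomo:::ball_offsets(1, 3)
  brute_erode <- array(FALSE, dim(m))
  brute_dilate <- array(FALSE, dim(m))
  for (i in 1:9) for (j in 1:9) for (k in 1:9) {
    vals <- logical(nrow(offs))
    for (o in seq_len(nrow(offs))) {
      p <- c(i, j, k) + offs[o, ]
      vals[o] <- all(p >= 1 & p <= 9) && m[p[1], p[2], p[3]]
    }
    brute_erode[i, j, k] <- all(vals)
    brute_dilate[i, j, k] <- any(vals)
  }
  expect_equal(binary_erode(m, 1), brute_erode)
  expect_equal(binary_dilate(m, 1), brute_dilate)

  ## idempotence of opening on random masks, 2D and 3D
  for (seed in 1:3) {
    set.seed(seed)
    m2 <- matrix(runif(30 * 30) > 0.55, 30)
    o1 <- binary_opening(m2, 2)
    expect_identical(binary_opening(o1, 2), o1)
  }
  ## isolated single-voxel speckle vanishes under a radius-2 element
  sp <- array(FALSE, c(15, 15)); sp[7, 7] <- TRUE
  expect_true(all(!binary_opening(sp, 2)))
})

test_that("bone separates from the attenuation image with high overlap", {
  ph <- make_bone_phantom(c(64L, 64L), 0.35e-3, bone_radius = 4e-3,
                          cortical_thickness = 1.4e-3, tissue_sos = 1570,
                          tissue_atten = 70)
  mask <- segment_bone_from_attenuation(ph$atten)
  truth <- attr(ph, "bone_mask")
  dice <- 2 * sum(mask & truth) / (sum(mask) + sum(truth))
  expect_gte(dice, 0.9)
  expect_warning(m0 <- segment_bone_from_attenuation(array(0, c(8, 8))),
                 "empty")
  expect_true(all(!m0))
  expect_error(segment_bone_from_attenuation(array(-1, c(4, 4))),
               "non-negative")
})

test_that("SOS-interval segmentation labels tabulated tissues", {
  ## a uniform slab at the measured fat speed is entirely fat
  seg <- segment_tissues_by_sos(matrix(1438.7, 8, 8))
  expect_true(all(seg$labels == seg$legend[["fat"]]))
  segw <- segment_tissues_by_sos(matrix(1500, 8, 8))
  expect_true(all(segw$labels == segw$legend[["water"]]))

  ## phantom with known layout: accuracy away from a 1-voxel boundary band
  layout <- list(list(tissue = "fat", center = c(-4e-3, -4e-3),
                      radius = 3e-3),
                 list(tissue = "muscle", center = c(4e-3, 4e-3),
                      radius = 3e-3))
  ph <- make_soft_tissue_phantom(c(64L, 64L), 0.35e-3, layout)
  seg2 <- segment_tissues_by_sos(ph$sos)
  truth_lab <- attr(ph, "labels")
  interior <- binary_erode(truth_lab == 1L, 1) |
    binary_erode(truth_lab == 2L, 1) | binary_erode(truth_lab == 0L, 1)
  want <- ifelse(truth_lab == 1L, seg2$legend[["fat"]],
          ifelse(truth_lab == 2L, seg2$legend[["muscle"]],
                 seg2$legend[["water"]]))
  acc <- mean(seg2$labels[interior] == want[interior])
  expect_gte(acc, 0.99)
  bad <- data.frame(label = c("a", "b"), lo = c(1, 2), hi = c(3, 2.5))
  expect_error(segment_tissues_by_sos(matrix(1, 2, 2), bad),
               "non-overlapping")
})

test_that("ROI statistics give exact small-sample moments and calibrated SD", {
  vol <- matrix(7, 40, 40)
  r <- roi_statistics(vol, 0.5e-3, c(0, 0), 6e-3)
  expect_equal(r$mean, 7)
  expect_equal(r$sd, 0)
  ## two-voxel closed form via a degenerate two-voxel ROI
  v2 <- matrix(c(3, 11), 1, 2)
  r2 <- roi_statistics(v2, c(10, 1e-3), c(0, 0), 2.5e-3)
  expect_equal(r2$n, 2L)
  expect_equal(r2$mean, 7)
  expect_equal(r2$sd, abs(3 - 11) / sqrt(2))
  ## Gaussian noise sigma recovered within 10% on ~700 voxels
  set.seed(31)
  noisy <- matrix(1500 + rnorm(120^2, sd = 20), 120)
  rn <- roi_statistics(noisy, 0.2e-3, c(0, 0), 6e-3)
  expect_gt(rn$n, 600)
  expect_lt(abs(rn$sd - 20) / 20, 0.1)
  expect_error(roi_statistics(vol, 0.5e-3, c(1, 1), 1e-3), "ROI")
  ## batch report pools slices
  vol3 <- array(5, c(20, 20, 3))
  rep3 <- roi_report(vol3, 0.5e-3,
                     list(list(name = "a", center = c(0, 0),
                               diameter = 3e-3, slices = 1:3)))
  expect_equal(rep3$mean, 5)
})

test_that("FWHM of analytic profiles matches closed forms", {
  h <- 0.2e-3
  x <- paraxtomo:::axis_coords(101, h)
  ## discrete Gaussian, sigma = 1 mm: FWHM = 2.355 mm
  g <- outer(exp(-x^2 / (2 * 1e-3^2)), rep(1, 7))
  f <- fwhm_profile(g, h, c(-8e-3, 0), c(8e-3, 0))
  expect_equal(f$fwhm_mm, 2 * sqrt(2 * log(2)), tolerance = 0.05)
  ## single-voxel spike: degenerate peak at most 2 voxels wide
  sp <- matrix(0, 51, 7); sp[26, 4] <- 1
  fs <- fwhm_profile(sp, h, c(-4e-3, 0), c(4e-3, 0))
  expect_lte(fs$fwhm_mm, 2 * h * 1e3)
  ## boxcar of width 3 mm: FWHM within one voxel of the width
  bx <- matrix(0, 101, 7); bx[abs(x) <= 1.5e-3, ] <- 1
  fb <- fwhm_profile(bx, h, c(-8e-3, 0), c(8e-3, 0))
  expect_lt(abs(fb$fwhm_mm - 3), h * 1e3 + 0.05)
  ## monotone profile has no peak
  mono <- outer(seq(0, 1, length.out = 51), rep(1, 5))
  expect_error(fwhm_profile(mono, h, c(-4e-3, 0), c(4e-3, 0)), "peak")
})
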