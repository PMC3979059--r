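test_that("volumes are voxel counts times voxel volume", {
  d <- c(20, 20, 20)
  m <- array(FALSE, d); m[1:10, 1:10, 1:10] <- TRUE  # 1000 voxels
  mask <- BinaryVolume(m, 6)
  roi <- RoiMask(array(TRUE, d), 6)
  expect_equal(boneVolume(mask, roi), 1000 * 0.006^3)
  expect_equal(boneVolume(BinaryVolume(array(FALSE, d), 6), roi), 0)
  expect_equal(totalVolume(RoiMask(m, 6)), 1000 * 0.006^3)
  expect_error(totalVolume(RoiMask(array(FALSE, d), 6)), "empty")
  expect_error(boneVolume(mask, RoiMask(array(TRUE, c(5, 5, 5)), 6)),
               "geometry mismatch")

  # digital ball vs an independent per-voxel counting oracle
  db <- ballArray(c(50, 50, 50), 20)
  coords <- expand.grid(i = 1:50, j = 1:50, k = 1:50)
  oracle <- sum((coords$i - 25.5)^2 + (coords$j - 25.5)^2 +
                  (coords$k - 25.5)^2 <= 400)
  expect_equal(boneVolume(BinaryVolume(db, 6), RoiMask(array(TRUE, dim(db)), 6)),
               oracle * 0.006^3)

  # cylinder ROI volume approaches pi r^2 h
  cyl <- tubeArray(c(30, 60, 60), 25, 0)
  expect_lt(abs(totalVolume(RoiMask(cyl, 6)) - pi * 0.15^2 * 0.18) /
              (pi * 0.15^2 * 0.18), 0.02)
})

test_that("iso-surface area tracks the analytic sphere across radii and phases", {
  # spheres at random sub-voxel centres: the area error stays within the
  # 3% band at every radius and its phase-induced scatter shrinks as the
  # radius grows (a small fixed-sign bias from residual voxelisation
  # roughness remains; see the methods vignette)
  relErr <- function(rvox, off) {
    d <- rep(2 * rvox + 16, 3)
    b <- ballArray(d, rvox, cen = (d + 1) / 2 + off)
    f <- gaussianFilter(DensityVolume(densityFromMask(b), 6), stdFilter())
    rmm <- rvox * 0.006
    (boneSurface(f, 500) - 4 * pi * rmm^2) / (4 * pi * rmm^2)
  }
  set.seed(99)
  offs <- matrix(runif(15, -0.5, 0.5), 5)
  e10 <- apply(offs, 1, function(o) relErr(10, o))
  e40 <- apply(offs, 1, function(o) relErr(40, o))
  expect_lt(max(abs(c(e10, e40))), 0.03)
  expect_lt(sd(e40), sd(e10))
})

test_that("surface is additive over disjoint regions and zero without bone", {
  d <- c(40, 40, 80)
  bone <- ballArray(d, 10, cen = c(20.5, 20.5, 20.5)) |
          ballArray(d, 10, cen = c(20.5, 20.5, 60.5))
  f <- gaussianFilter(DensityVolume(densityFromMask(bone), 6), stdFilter())
  left <- array(FALSE, d); left[, , 1:40] <- TRUE
  right <- !left
  whole <- boneSurface(f, 500)
  parts <- boneSurface(f, 500, RoiMask(left, 6)) +
           boneSurface(f, 500, RoiMask(right, 6))
  expect_equal(whole, parts, tolerance = 1e-9)
  empty <- array(FALSE, d); empty[1:4, 1:4, 1:4] <- TRUE
  expect_equal(boneSurface(f, 500, RoiMask(empty, 6)), 0)
})

test_that("local thickness recovers plates, balls and rods", {
  # plate of 10 slices: exactly 10 voxels = 0.060 mm away from edges
  p <- makePhantom(phantomSpec("plate", list(thickness = 0.06),
                               dim = c(40, 60, 60), noiseSd = 0))
  mask <- segmentBone(p$volume, 500)
  roi <- RoiMask({a <- array(FALSE, dim(mask)); a[, 15:45, 15:45] <- TRUE; a}, 6)
  expect_lt(abs(trabecularThickness(mask, roi) - 0.060), 0.006)

  # ball: central thickness ~ diameter
  b <- ballArray(c(40, 40, 40), 15)
  th <- localThickness(BinaryVolume(b, 6))
  expect_lt(abs(th[20, 20, 20] / 0.006 - 30), 2.5)

  # rod lattice: mean within 15% of the rod diameter
  rl <- makePhantom(phantomSpec("rod_lattice",
                                list(rod_diameter = 0.048, spacing = 0.12),
                                dim = c(40, 96, 96), noiseSd = 0))
  rmask <- segmentBone(rl$volume, 500)
  rroi <- RoiMask({a <- array(FALSE, dim(rmask)); a[10:30, , ] <- TRUE; a}, 6)
  expect_lt(abs(trabecularThickness(rmask, rroi) - 0.048) / 0.048, 0.15)
})

test_that("cortical thickness of shells matches R - r within one voxel", {
  d <- c(30, 130, 130)
  shell <- BinaryVolume(tubeArray(d, 60, 40), 6)
  slab <- RoiMask({a <- array(FALSE, d); a[8:23, , ] <- TRUE; a}, 6)
  expect_lt(abs(corticalThickness(shell, slab) - 0.120), 0.006)

  thin <- BinaryVolume(tubeArray(c(10, 40, 40), 15, 14), 6)
  slab2 <- RoiMask({a <- array(FALSE, c(10, 40, 40)); a[3:8, , ] <- TRUE; a}, 6)
  th1 <- corticalThickness(thin, slab2) / 0.006
  expect_gt(th1, 0.5); expect_lt(th1, 2.5)  # one-voxel wall

  solid <- BinaryVolume(tubeArray(c(40, 70, 70), 25, 0), 6)
  th <- localThickness(solid)
  expect_lt(abs(th[20, 35, 35] / 0.006 - 50), 3)  # diameter-limited centre
})

test_that("marrow + cortical volume equals the total diaphysis volume exactly", {
  d <- c(100, 110, 110)
  shell <- BinaryVolume(tubeArray(d, 50, 40), 6)
  slab <- RoiMask(array(TRUE, d), 6)
  mt <- marrowAndTotalVolume(shell, slab)
  analytic <- pi * 0.24^2 * 0.6
  expect_lt(abs(mt[["marrow"]] - analytic) / analytic, 0.02)
  bv <- boneVolume(shell, slab)
  expect_equal(mt[["total"]] - mt[["marrow"]], bv, tolerance = 1e-12)

  solid <- BinaryVolume(tubeArray(d, 30, 0), 6)
  mts <- marrowAndTotalVolume(solid, slab)
  expect_equal(mts[["marrow"]], 0)
  expect_equal(mts[["total"]], boneVolume(solid, slab))
})

test_that("phantom BV/TV matches the declared fill fraction", {
  # plate: fill = slices occupied / slab slices, exact by construction
  p <- makePhantom(phantomSpec("plate", list(thickness = 0.06),
                               dim = c(30, 40, 40), noiseSd = 0))
  f <- gaussianFilter(p$volume, stdFilter())
  mask <- segmentBone(f, 500)
  roi <- fullRoi(p$volume)
  expect_equal(boneVolume(mask, roi) / totalVolume(roi), 10 / 30,
               tolerance = 0.02)

  # rod lattice over an integral number of unit cells
  rl <- makePhantom(phantomSpec("rod_lattice",
                                list(rod_diameter = 0.06, spacing = 0.12),
                                dim = c(24, 96, 96), noiseSd = 0))
  fm <- segmentBone(gaussianFilter(rl$volume, stdFilter()), 500)
  cell <- array(FALSE, c(24, 96, 96))
  cell[, 19:78, 19:78] <- TRUE   # 3 x 3 cells of 20 voxels around centres
  roi2 <- RoiMask(cell, 6)
  bvtv <- boneVolume(fm, roi2) / totalVolume(roi2)
  expect_lt(abs(bvtv - rl$truth$fill_fraction) / rl$truth$fill_fraction, 0.02)
})

test_that("thickness is stable under voxel-size refinement", {
  tb <- function(vs) {
    p <- makePhantom(phantomSpec("rod_lattice",
                                 list(rod_diameter = 0.09, spacing = 0.18),
                                 dim = c(20, round(720 / vs), round(720 / vs)),
                                 noiseSd = 0, voxelSize = vs))
    m <- segmentBone(p$volume, 500)
    roi <- RoiMask({a <- array(FALSE, dim(m)); a[5:15, , ] <- TRUE; a}, vs)
    trabecularThickness(m, roi)
  }
  expect_lt(abs(tb(6) - tb(3)) / tb(6), 0.05)
})

test_that("extensive quantities add over disjoint ROIs", {
  p <- makePhantom(phantomSpec("sphere", list(radius = 0.12),
                               noiseSd = 0, seed = 2))
  f <- gaussianFilter(p$volume, stdFilter())
  mask <- segmentBone(f, 500)
  d <- dim(p$volume)
  a <- array(FALSE, d); a[1:(d[1] / 2), , ] <- TRUE
  roiA <- RoiMask(a, 6); roiB <- RoiMask(!a, 6); whole <- fullRoi(p$volume)
  expect_equal(boneVolume(mask, roiA) + boneVolume(mask, roiB),
               boneVolume(mask, whole), tolerance = 1e-12)
  expect_equal(totalVolume(roiA) + totalVolume(roiB), totalVolume(whole),
               tolerance = 1e-12)
})
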