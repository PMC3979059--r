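test_that("surface density is BS/BV with a guarded denominator", {
  expect_equal(surfaceDensity(2, 1), 2)
  expect_error(surfaceDensity(1, 0), "positive")

  # sphere: BS/BV = 3/r
  p <- makePhantom(phantomSpec("sphere", list(radius = 0.18),
                               noiseSd = 0, seed = 1))
  f <- gaussianFilter(p$volume, stdFilter())
  roi <- fullRoi(p$volume)
  sd1 <- surfaceDensity(boneSurface(f, 500, roi),
                        boneVolume(segmentBone(f, 500), roi))
  expect_lt(abs(sd1 - 3 / 0.18) / (3 / 0.18), 0.05)

  # plate with lateral faces excluded by ROI clipping: BS/BV = 2/t
  pl <- makePhantom(phantomSpec("plate", list(thickness = 0.09),
                                dim = c(50, 60, 60), noiseSd = 0))
  fp <- gaussianFilter(pl$volume, stdFilter())
  inner <- array(FALSE, c(50, 60, 60)); inner[, 10:50, 10:50] <- TRUE
  roi2 <- RoiMask(inner, 6)
  sd2 <- surfaceDensity(boneSurface(fp, 500, roi2),
                        boneVolume(segmentBone(fp, 500), roi2))
  expect_lt(abs(sd2 - 2 / 0.09) / (2 / 0.09), 0.05)
})

test_that("smoothness is near one for smooth spheres and scale-stable", {
  sm <- function(radius, seed = 1) {
    p <- makePhantom(phantomSpec("sphere", list(radius = radius),
                                 seed = seed))
    smoothnessEstimator(p$volume)$smoothness
  }
  s1 <- sm(0.18)
  expect_gt(s1, 0.95)
  s2 <- sm(0.36)  # doubling the radius changes smoothness by < 2%
  expect_lt(abs(s2 - s1) / s1, 0.02)
})

test_that("pitting lowers smoothness and raises BS/BV at fixed geometry", {
  est <- function(pd, seed = 11) {
    p <- makePhantom(phantomSpec("pitted_sphere", list(radius = 0.45),
                                 pitDensity = pd, seed = seed))
    smoothnessEstimator(p$volume)
  }
  e0 <- est(0); e5 <- est(5); e10 <- est(10)
  expect_lt(e5$smoothness, e0$smoothness)
  expect_lt(e10$smoothness, e5$smoothness)
  expect_gt(e5$BS_over_BV, e0$BS_over_BV)
  expect_gt(e10$BS_over_BV, e5$BS_over_BV)
  expect_lt(e10$BV, e0$BV)
})

test_that("the rough limit collapses smoothness off the density knife-edge", {
  # bone probability 0.4: the strongly smoothed field pulls clear of the
  # threshold and nearly all iso-surface disappears
  p <- makePhantom(phantomSpec("speckle", list(bone_probability = 0.4),
                               dim = c(96, 96, 96), seed = 1))
  es <- smoothnessEstimator(p$volume)
  expect_lt(es$smoothness, 0.05)

  # symmetric speckle stays far rougher than any smooth structure
  p5 <- makePhantom(phantomSpec("speckle", list(bone_probability = 0.5),
                                dim = c(96, 96, 96), seed = 1))
  sphere <- makePhantom(phantomSpec("sphere", list(radius = 0.18), seed = 1))
  expect_lt(smoothnessEstimator(p5$volume)$smoothness,
            0.5 * smoothnessEstimator(sphere$volume)$smoothness)
})

test_that("smoothness is zero when strong filtering erases all structure", {
  d <- c(24, 24, 24)
  bone <- array(FALSE, d); bone[12:14, 12:14, 12:14] <- TRUE  # 3^3 speck
  vol <- DensityVolume(densityFromMask(bone), 6)
  es <- smoothnessEstimator(vol)
  expect_gt(es$BS, 0)
  expect_identical(es$BS_smooth, 0)
  expect_identical(es$smoothness, 0)
  # no surface at all under standard filtering is an error
  flat <- DensityVolume(array(100, d), 6)
  expect_error(smoothnessEstimator(flat), "no bone surface")
})

test_that("endosteal apposition moves BS/BV but not smoothness (dissociation)", {
  est <- function(innerR) {
    p <- makePhantom(phantomSpec(
      "pitted_tube", list(outer_radius = 0.30, inner_radius = innerR,
                          length = 0.45),
      dim = c(75, 116, 116), pitDensity = 5, seed = 5))
    smoothnessEstimator(p$volume)
  }
  base <- est(0.24)
  appo <- est(0.24 / sqrt(1.6))   # marrow volume reduced 1.6-fold
  expect_gt(abs(appo$BS_over_BV - base$BS_over_BV) / base$BS_over_BV, 0.10)
  expect_lt(abs(appo$smoothness - base$smoothness) / base$smoothness, 0.02)
})
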