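# independent direct-convolution oracle: dense triple loop with the same
# contract (sampled truncated kernel, renormalised, mirror boundaries)
directGauss3 <- function(arr, sigma, support) {
  k <- exp(-(-support:support)^2 / (2 * sigma^2))
  k <- k / sum(k)
  refl <- function(i, n) {
    i <- ((i - 1) %% (2 * n)); i[i < 0] <- i[i < 0] + 2 * n
    ifelse(i >= n, 2 * n - 1 - i, i) + 1
  }
  d <- dim(arr)
  out <- array(0, d)
  off <- -support:support
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (l in seq_len(d[3])) {
    acc <- 0
    for (a in seq_along(off)) for (b in seq_along(off)) for (cc in seq_along(off)) {
      acc <- acc + k[a] * k[b] * k[cc] *
        arr[refl(i + off[a], d[1]), refl(j + off[b], d[2]),
            refl(l + off[cc], d[3])]
    }
    out[i, j, l] <- acc
  }
  out
}

test_that("sigma zero is the identity and constants are preserved exactly", {
  set.seed(1)
  arr <- array(runif(64, 0, 1200), c(4, 4, 4))
  vol <- DensityVolume(arr, 6)
  expect_identical(volData(gaussianFilter(vol, filterParams(0, 1))), arr)
  expect_identical(volData(gaussianFilter(vol, filterParams(0.8, 0))), arr)

  const <- DensityVolume(array(500, c(6, 6, 6)), 6)
  expect_equal(volData(gaussianFilter(const, stdFilter())),
               array(500, c(6, 6, 6)), tolerance = 1e-14)
  expect_error(filterParams(-1, 1), "non-negative")
})

test_that("the filter matches a direct-convolution oracle on an impulse", {
  arr <- array(0, c(9, 9, 9))
  arr[5, 5, 5] <- 1
  vol <- DensityVolume(arr, 6)
  for (fp in list(filterParams(2.5, 5), stdFilter())) {
    got <- volData(gaussianFilter(vol, fp))
    want <- directGauss3(arr, fp@sigma, fp@support)
    expect_lt(max(abs(got - want)) / max(abs(want)), 1e-10)
  }
  # off-centre impulse exercises the mirror boundary
  arr2 <- array(0, c(9, 9, 9)); arr2[2, 3, 9] <- 1
  got <- volData(gaussianFilter(DensityVolume(arr2, 6), filterParams(2.5, 5)))
  want <- directGauss3(arr2, 2.5, 5)
  expect_lt(max(abs(got - want)) / max(abs(want)), 1e-10)
})

test_that("the filter is linear and shift-equivariant in the interior", {
  set.seed(2)
  d <- c(12, 12, 12)
  X <- array(runif(prod(d)), d); Y <- array(runif(prod(d)), d)
  fp <- stdFilter()
  f <- function(a) volData(gaussianFilter(DensityVolume(a, 6), fp))
  expect_equal(f(2 * X + 3 * Y), 2 * f(X) + 3 * f(Y), tolerance = 1e-12)

  imp <- function(pos) { a <- array(0, c(15, 15, 15)); a[pos, pos, pos] <- 1; a }
  r1 <- f2 <- volData(gaussianFilter(DensityVolume(imp(6), 6),
                                     filterParams(1.5, 3)))
  r2 <- volData(gaussianFilter(DensityVolume(imp(9), 6),
                               filterParams(1.5, 3)))
  expect_equal(r1[3:9, 3:9, 3:9], r2[6:12, 6:12, 6:12], tolerance = 1e-14)
})

test_that("segmentation threshold is inclusive and monotone", {
  v499 <- DensityVolume(array(499, c(4, 4, 4)), 6)
  v500 <- DensityVolume(array(500, c(4, 4, 4)), 6)
  expect_false(any(volData(segmentBone(v499, segmentationParams(500)))))
  expect_true(all(volData(segmentBone(v500, segmentationParams(500)))))

  set.seed(3)
  v <- DensityVolume(array(runif(1000, 0, 1000), c(10, 10, 10)), 6)
  m4 <- volData(segmentBone(v, 400))
  m5 <- volData(segmentBone(v, 500))
  m6 <- volData(segmentBone(v, 600))
  expect_true(all(m6 <= m5) && all(m5 <= m4))  # raising threshold removes only

  # idempotence through re-segmentation of the mask rendered as density
  md <- DensityVolume(m5 * 900, 6)
  expect_identical(volData(segmentBone(md, 500)), m5)
})

test_that("segmenting the filtered sphere phantom recovers the analytic ball volume", {
  p <- makePhantom(phantomSpec("sphere", list(radius = 0.18),
                               noiseSd = 0, seed = 1))
  f <- gaussianFilter(p$volume, stdFilter())
  mask <- segmentBone(f, segmentationParams(500))
  analytic <- 4 / 3 * pi * 30^3   # voxels, r = 30
  expect_lt(abs(sum(volData(mask)) - analytic) / analytic, 0.02)
})
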