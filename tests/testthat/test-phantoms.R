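test_that("phantom generation is deterministic and seed-separable", {
  sp <- phantomSpec("pitted_sphere", list(radius = 0.12), pitDensity = 10,
                    seed = 4)
  a <- makePhantom(sp); b <- makePhantom(sp)
  expect_identical(volData(a$volume), volData(b$volume))
  expect_identical(a$truth, b$truth)

  # a different seed moves only noise and pits, not the analytic record
  sp2 <- phantomSpec("pitted_sphere", list(radius = 0.12), pitDensity = 10,
                     seed = 5)
  c2 <- makePhantom(sp2)
  expect_false(identical(volData(a$volume), volData(c2$volume)))
  expect_identical(a$truth$BS_mm2, c2$truth$BS_mm2)
  expect_identical(a$truth$BV_mm3, c2$truth$BV_mm3)
})

test_that("noise-free spheres match the per-voxel membership oracle", {
  p <- makePhantom(phantomSpec("sphere", list(radius = 0.09),
                               noiseSd = 0, seed = 1))
  d <- dim(p$volume)
  oracle <- ballArray(d, 15)
  expect_identical(volData(p$volume) == 900, oracle)
  expect_identical(p$truth$n_bone_voxels, sum(oracle))
  expect_gte(sum(oracle), 4 / 3 * pi * (15 - 1)^3)  # analytic lower bound
})

test_that("pit counts are Poisson with the configured surface intensity", {
  lambda <- 20 * 4 * pi * 0.15^2   # density 20 / mm^2 on an r = 0.15 sphere
  counts <- vapply(1:50, function(s) {
    makePhantom(phantomSpec("pitted_sphere", list(radius = 0.15),
                            pitDensity = 20, noiseSd = 0,
                            seed = s))$truth$pit_count
  }, 1L)
  expect_lt(abs(mean(counts) - lambda) / lambda, 0.15)
  expect_gt(var(counts), 0)
})

test_that("study bookkeeping, effect sizes and self-consistency", {
  st <- makeStudy(groupSizes = c(CTR = 5L, CIA_PBS = 5L, CIA_SclAbI = 5L),
                  lateral = 40L,
                  sections = c(joint = 12L, metaphysis = 12L, diaphysis = 12L),
                  outerRadius = 0.09, innerRadius = 0.07,
                  rodDiameter = 0.024, rodSpacing = 0.05,
                  thinningFactor = 0.8, marrowFoldChange = 1.6,
                  noiseSd = 0)
  expect_length(st$volumes, 15)
  expect_identical(table(st$truth$group)[c("CTR", "CIA_PBS", "CIA_SclAbI")],
                   table(factor(rep(c("CTR", "CIA_PBS", "CIA_SclAbI"),
                                    each = 5)))[c("CTR", "CIA_PBS",
                                                  "CIA_SclAbI")])
  expect_identical(unique(st$truth$thinning_factor[st$truth$group == "CIA_PBS"]),
                   0.8)
  expect_identical(unique(st$truth$pit_density[st$truth$group == "CTR"]), 0)

  # configured marrow fold-change is exact in the truth table
  mCtr <- st$truth$marrow_volume_mm3[st$truth$group == "CTR"][1]
  mApp <- st$truth$marrow_volume_mm3[st$truth$group == "CIA_SclAbI"][1]
  expect_equal(mCtr / mApp, 1.6, tolerance = 1e-9)

  # reproducibility under the master seed
  st2 <- makeStudy(groupSizes = c(CTR = 1L, CIA_PBS = 1L, CIA_SclAbI = 1L),
                   lateral = 40L,
                   sections = c(joint = 12L, metaphysis = 12L,
                                diaphysis = 12L),
                   outerRadius = 0.09, innerRadius = 0.07,
                   rodDiameter = 0.024, rodSpacing = 0.05, seed = 9L)
  st3 <- makeStudy(groupSizes = c(CTR = 1L, CIA_PBS = 1L, CIA_SclAbI = 1L),
                   lateral = 40L,
                   sections = c(joint = 12L, metaphysis = 12L,
                                diaphysis = 12L),
                   outerRadius = 0.09, innerRadius = 0.07,
                   rodDiameter = 0.024, rodSpacing = 0.05, seed = 9L)
  expect_identical(volData(st2$volumes[[2]]), volData(st3$volumes[[2]]))
})

test_that("null effect parameters make the groups exchangeable", {
  st <- makeStudy(groupSizes = c(CTR = 2L, CIA_PBS = 2L, CIA_SclAbI = 2L),
                  lateral = 40L,
                  sections = c(joint = 12L, metaphysis = 12L, diaphysis = 12L),
                  outerRadius = 0.09, innerRadius = 0.07,
                  rodDiameter = 0.024, rodSpacing = 0.05,
                  thinningFactor = 1, marrowFoldChange = 1, pitDensity = 0)
  tr <- st$truth
  expect_identical(unique(tr$rod_diameter_mm), 0.024)
  expect_identical(unique(tr$inner_radius_shaft_mm), 0.07)
  expect_identical(unique(tr$pit_density), 0)
  expect_identical(unique(tr$pit_count), 0L)
})

test_that("non-physical effect parameters are rejected", {
  expect_error(makeStudy(groupSizes = c(CTR = 1L, CIA_PBS = 1L,
                                        CIA_SclAbI = 1L),
                         marrowFoldChange = 400),
               "non-physical inner radius")
  expect_error(makeStudy(groupSizes = c(CTR = 0L, CIA_PBS = 1L,
                                        CIA_SclAbI = 1L)),
               ">= 1")
  expect_error(phantomSpec("sphere", list(radius = -1)), "positive")
  expect_error(makePhantom(phantomSpec("sphere", list(radius = 0.5),
                                       dim = c(20, 20, 20))),
               "does not fit")
})
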