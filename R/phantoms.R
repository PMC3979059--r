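## Synthetic bone phantoms with ground truth.
##
## Every phantom is an analytic solid voxelised at voxel centres, mapped to
## bone/background densities, with independent Gaussian scanner noise added
## everywhere. Defaults (bone 900, background 100, noise sd 60 mg HA/cm^3)
## are plausible murine cortical values bracketing the conventional
## 500 mg HA/cm^3 threshold with ~6-7 noise SDs of separation, so the fixed
## threshold is discriminative. Generation is fully deterministic given the
## spec (seed included); changing only the seed changes only noise and pit
## placement, never the analytic geometry.
##
## Pits are hemispherical indentations centred on the analytic surface,
## with Poisson-distributed count at `pitDensity` pits per mm^2 of analytic
## surface - the simplest model of superficial pitting of periarticular
## bone.

#' Phantom specification constructor
#'
#' @param family phantom family (see \linkS4class{PhantomSpec}).
#' @param geometry named list of family-specific lengths in mm:
#'   \code{radius} (sphere), \code{thickness} (plate),
#'   \code{rod_diameter} and \code{spacing} (rod_lattice),
#'   \code{outer_radius}, \code{inner_radius} and optional \code{length}
#'   (tubes), \code{bone_probability} (speckle).
#' @param dim grid dimensions (slices, rows, cols); when NULL a grid
#'   enclosing the geometry with an 8-voxel margin is chosen.
#' @param boneDensity,backgroundDensity,noiseSd densities, mg HA/cm^3.
#' @param pitDensity pits per mm^2 of analytic surface (pitted families).
#' @param pitRadius hemispherical pit radius, mm.
#' @param voxelSize voxel size, micrometres.
#' @param seed integer RNG seed.
#' @return A \linkS4class{PhantomSpec}.
#' @examples
#' phantomSpec("sphere", list(radius = 0.18), seed = 1)
#' @export
phantomSpec <- function(family, geometry = list(), dim = NULL,
                        boneDensity = 900, backgroundDensity = 100,
                        noiseSd = 60, pitDensity = 0, pitRadius = 0.03,
                        voxelSize = 6, seed = 1L) {
  vox <- voxelSize / 1000  # mm per voxel
  toVox <- function(mm) mm / vox
  if (is.null(dim)) {
    margin <- 16L
    side <- switch(family,
      sphere = ,
      pitted_sphere = 2 * ceiling(toVox(geometry$radius)) + margin,
      plate = NULL,
      rod_lattice = NULL,
      cortical_tube = ,
      pitted_tube = 2 * ceiling(toVox(geometry$outer_radius)) + margin,
      speckle = 64L)
    dim <- switch(family,
      sphere = ,
      pitted_sphere = rep(side, 3L),
      plate = c(2 * ceiling(toVox(geometry$thickness)) + margin, 96L, 96L),
      rod_lattice = c(64L, 96L, 96L),
      cortical_tube = ,
      pitted_tube = c(
        if (!is.null(geometry$length))
          ceiling(toVox(geometry$length)) else 64L, side, side),
      speckle = rep(side, 3L))
  }
  new("PhantomSpec", family = family, geometry = geometry,
      gridDim = as.integer(dim), boneDensity = boneDensity,
      backgroundDensity = backgroundDensity, noiseSd = noiseSd,
      pitDensity = pitDensity, pitRadius = pitRadius,
      voxelSize = voxelSize, seed = as.integer(seed))
}

# squared lateral radius map (rows x cols), distances in voxels
.lat2 <- function(n2, n3, c2, c3) {
  outer((seq_len(n2) - c2)^2, (seq_len(n3) - c3)^2, "+")
}

# replicate a lateral quantity over all slices as an (n1, n2, n3) array
.overSlices <- function(latMat, n1) {
  aperm(array(latMat, c(dim(latMat), n1)), c(3, 1, 2))
}

# carve a spherical pit of radius pr (voxels) centred at p (voxels)
.carvePit <- function(bone, p, pr) {
  d <- dim(bone)
  lo <- pmax(1L, floor(p - pr)); hi <- pmin(d, ceiling(p + pr))
  if (any(lo > hi)) return(bone)
  i <- lo[1]:hi[1]; j <- lo[2]:hi[2]; k <- lo[3]:hi[3]
  d2 <- outer(outer((i - p[1])^2, (j - p[2])^2, "+"), (k - p[3])^2, "+")
  bone[i, j, k] <- bone[i, j, k] & (d2 > pr^2)
  bone
}

#' Generate a phantom volume with its ground-truth record
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return List with elements \code{volume} (a
#'   \linkS4class{DensityVolume}) and \code{truth} (a one-row data.frame
#'   carrying the analytic bone volume, surface, thickness, marrow volume
#'   and fill fraction where closed forms exist, the realised pit count,
#'   and the voxelised bone-voxel count).
#' @examples
#' p <- makePhantom(phantomSpec("sphere", list(radius = 0.06),
#'                              noiseSd = 0, seed = 1))
#' p$truth$BS_mm2  # 4 * pi * 0.06^2
#' @export
makePhantom <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  d <- spec@gridDim
  n1 <- d[1]; n2 <- d[2]; n3 <- d[3]
  vox <- spec@voxelSize / 1000
  toVox <- function(mm) mm / vox
  g <- spec@geometry
  c1 <- (n1 + 1) / 2; c2 <- (n2 + 1) / 2; c3 <- (n3 + 1) / 2
  set.seed(spec@seed)

  truth <- data.frame(family = spec@family, seed = spec@seed,
                      voxel_size_um = spec@voxelSize,
                      BV_mm3 = NA_real_, BS_mm2 = NA_real_,
                      thickness_mm = NA_real_, fill_fraction = NA_real_,
                      marrow_mm3 = NA_real_, total_mm3 = NA_real_,
                      pit_count = NA_integer_,
                      pit_density = spec@pitDensity,
                      n_bone_voxels = NA_integer_)
  pitR <- toVox(spec@pitRadius)

  bone <- switch(spec@family,
    sphere = ,
    pitted_sphere = {
      r <- toVox(g$radius)
      if (2 * r + 2 > min(d)) stop("sphere does not fit the grid")
      lat <- .lat2(n2, n3, c2, c3)
      b <- outer((seq_len(n1) - c1)^2, lat, "+") <= r^2
      dim(b) <- d
      truth$BV_mm3 <- 4 / 3 * pi * g$radius^3
      truth$BS_mm2 <- 4 * pi * g$radius^2
      truth$thickness_mm <- 2 * g$radius
      if (spec@family == "pitted_sphere") {
        nPits <- rpois(1, spec@pitDensity * truth$BS_mm2)
        truth$pit_count <- nPits
        if (nPits > 0) for (q in seq_len(nPits)) {
          u <- rnorm(3); u <- u / sqrt(sum(u^2))
          b <- .carvePit(b, c(c1, c2, c3) + r * u, pitR)
        }
      } else truth$pit_count <- 0L
      b
    },
    plate = {
      nt <- .roundHalfAway(toVox(g$thickness))
      if (nt < 1 || nt > n1 - 2) stop("plate does not fit the grid")
      i0 <- floor(c1 - nt / 2) + 1
      b <- array(FALSE, d)
      b[i0:(i0 + nt - 1), , ] <- TRUE
      truth$thickness_mm <- nt * vox
      truth$BS_mm2 <- 2 * (n2 * n3) * vox^2
      truth$BV_mm3 <- nt * n2 * n3 * vox^3
      b
    },
    rod_lattice = {
      rd <- toVox(g$rod_diameter); sp <- toVox(g$spacing)
      if (rd >= sp) stop("rod diameter must be below the lattice spacing")
      ctr2 <- c2 + sp * (seq(-ceiling(n2 / sp), ceiling(n2 / sp)))
      ctr3 <- c3 + sp * (seq(-ceiling(n3 / sp), ceiling(n3 / sp)))
      ctr2 <- ctr2[ctr2 > rd / 2 + 1 & ctr2 < n2 - rd / 2]
      ctr3 <- ctr3[ctr3 > rd / 2 + 1 & ctr3 < n3 - rd / 2]
      lat <- matrix(FALSE, n2, n3)
      for (a in ctr2) for (bb in ctr3)
        lat <- lat | (.lat2(n2, n3, a, bb) <= (rd / 2)^2)
      truth$thickness_mm <- g$rod_diameter
      truth$fill_fraction <- pi * g$rod_diameter^2 / (4 * g$spacing^2)
      .overSlices(lat, n1)
    },
    cortical_tube = ,
    pitted_tube = {
      R <- toVox(g$outer_radius); r <- toVox(g$inner_radius)
      if (r >= R) stop("inner radius must be below outer radius")
      if (2 * R + 2 > min(n2, n3)) stop("tube does not fit the grid")
      nL <- if (!is.null(g$length))
        min(n1, .roundHalfAway(toVox(g$length))) else n1
      lat <- .lat2(n2, n3, c2, c3)
      latB <- lat <= R^2 & lat > r^2
      b <- array(FALSE, d)
      i0 <- floor(c1 - nL / 2) + 1
      slc <- i0:(i0 + nL - 1)
      for (k in slc) b[k, , ] <- latB
      Lmm <- nL * vox
      truth$thickness_mm <- g$outer_radius - g$inner_radius
      truth$BV_mm3 <- pi * (g$outer_radius^2 - g$inner_radius^2) * Lmm
      truth$marrow_mm3 <- pi * g$inner_radius^2 * Lmm
      truth$total_mm3 <- pi * g$outer_radius^2 * Lmm
      truth$BS_mm2 <- 2 * pi * (g$outer_radius + g$inner_radius) * Lmm
      if (spec@family == "pitted_tube") {
        outerA <- 2 * pi * g$outer_radius * Lmm
        nPits <- rpois(1, spec@pitDensity * outerA)
        truth$pit_count <- nPits
        if (nPits > 0) for (q in seq_len(nPits)) {
          z <- runif(1, min(slc), max(slc))
          th <- runif(1, 0, 2 * pi)
          b <- .carvePit(b, c(z, c2 + R * cos(th), c3 + R * sin(th)), pitR)
        }
      } else truth$pit_count <- 0L
      b
    },
    speckle = {
      p <- if (!is.null(g$bone_probability)) g$bone_probability else 0.5
      truth$fill_fraction <- p
      array(runif(prod(d)) < p, d)
    },
    stop("unknown phantom family: ", spec@family))

  truth$n_bone_voxels <- sum(bone)
  vals <- ifelse(bone, spec@boneDensity, spec@backgroundDensity)
  if (spec@noiseSd > 0)
    vals <- vals + rnorm(length(vals), 0, spec@noiseSd)
  vol <- DensityVolume(array(vals, d), spec@voxelSize,
                       name = sprintf("%s_seed%d", spec@family, spec@seed))
  list(volume = vol, truth = truth)
}

## ---- composite tibia-like phantom and the three-group study --------------

# Composite phantom along the slice axis: [joint | metaphysis | diaphysis].
# Joint: cortical tube with optional superficial pitting of the outer
# (periosteal) surface. Metaphysis: same tube with a trabecular rod lattice
# inside (2-voxel endosteal clearance so shell and trabeculae are
# disconnected). Diaphysis: plain tube whose inner radius sets the marrow
# volume. All lengths in mm.
.tibiaPhantom <- function(lateral = 128L,
                          sections = c(joint = 100L, metaphysis = 100L,
                                       diaphysis = 100L),
                          outerRadius = 0.30, innerRadius = 0.24,
                          innerRadiusShaft = innerRadius,
                          rodDiameter = 0.06, rodSpacing = 0.12,
                          pitDensity = 0, pitRadius = 0.03,
                          boneDensity = 900, backgroundDensity = 100,
                          noiseSd = 60, voxelSize = 6, seed = 1L) {
  vox <- voxelSize / 1000
  toVox <- function(mm) mm / vox
  nj <- sections[["joint"]]; nm <- sections[["metaphysis"]]
  nd <- sections[["diaphysis"]]
  n1 <- nj + nm + nd; n2 <- lateral; n3 <- lateral
  R <- toVox(outerRadius); rIn <- toVox(innerRadius)
  rShaft <- toVox(innerRadiusShaft)
  rd <- toVox(rodDiameter); sp <- toVox(rodSpacing)
  if (2 * R + 2 > lateral) stop("tube does not fit the lateral grid")
  if (rShaft < 2) stop("endosteal apposition closes the marrow cavity")
  if (rd <= 0) stop("non-physical rod diameter")
  c2 <- (n2 + 1) / 2; c3 <- (n3 + 1) / 2
  set.seed(as.integer(seed))

  lat <- .lat2(n2, n3, c2, c3)
  shellJoint <- lat <= R^2 & lat > rShaft^2
  shellMeta <- lat <= R^2 & lat > rIn^2
  # rod lattice restricted to the endosteal space, 2-voxel clearance
  rmax <- rIn - 2 - rd / 2
  ctrs <- sp * seq(-ceiling(rIn / sp), ceiling(rIn / sp))
  rods <- matrix(FALSE, n2, n3)
  for (a in ctrs) for (b in ctrs)
    if (sqrt(a^2 + b^2) <= rmax)
      rods <- rods | (.lat2(n2, n3, c2 + a, c3 + b) <= (rd / 2)^2)

  bone <- array(FALSE, c(n1, n2, n3))
  for (k in seq_len(nj)) bone[k, , ] <- shellJoint
  for (k in nj + seq_len(nm)) bone[k, , ] <- shellMeta | rods
  for (k in nj + nm + seq_len(nd)) bone[k, , ] <- shellJoint

  outerAreaJoint <- 2 * pi * outerRadius * (nj * vox)
  nPits <- if (pitDensity > 0) rpois(1, pitDensity * outerAreaJoint) else 0L
  if (nPits > 0) for (q in seq_len(nPits)) {
    z <- runif(1, 1, nj)
    th <- runif(1, 0, 2 * pi)
    bone <- .carvePit(bone, c(z, c2 + R * cos(th), c3 + R * sin(th)),
                      toVox(pitRadius))
  }

  vals <- ifelse(bone, boneDensity, backgroundDensity)
  if (noiseSd > 0) vals <- vals + rnorm(length(vals), 0, noiseSd)
  list(volume = DensityVolume(array(vals, c(n1, n2, n3)), voxelSize),
       landmark = nj + 1L,      # growth plate: first metaphysis slice
       sections = c(joint = nj, metaphysis = nm, diaphysis = nd),
       pit_count = nPits)
}

#' Generate a three-group synthetic study
#'
#' Emulates a healthy control / arthritic / antibody-treated design:
#' \code{CIA_PBS} samples carry trabecular thinning (rod diameter scaled
#' by \code{thinningFactor}) and superficial pitting of the periarticular
#' surface at \code{pitDensity}; \code{CIA_SclAbI} samples carry the same
#' pitting but no thinning, plus endosteal apposition reducing the shaft
#' marrow volume by \code{marrowFoldChange}; \code{CTR} samples are
#' unperturbed. Per-sample seeds are derived reproducibly from the master
#' seed.
#'
#' @param groupSizes named integer vector of samples per group, names
#'   \code{CTR}, \code{CIA_PBS}, \code{CIA_SclAbI}.
#' @param thinningFactor multiplicative trabecular thinning (1 = none).
#' @param marrowFoldChange fold-decrease of the shaft marrow volume under
#'   apposition (1 = none).
#' @param pitDensity pits per mm^2 of periosteal joint surface in the two
#'   arthritic groups.
#' @param pitRadius hemispherical pit radius, mm.
#' @param lateral,sections grid layout: lateral side (voxels) and named
#'   slice counts for the joint, metaphysis and diaphysis segments.
#' @param outerRadius,innerRadius cortical tube radii, mm.
#' @param rodDiameter,rodSpacing trabecular rod lattice, mm.
#' @param boneDensity,backgroundDensity,noiseSd densities, mg HA/cm^3.
#' @param voxelSize voxel size, micrometres.
#' @param seed master seed.
#' @return List with \code{volumes} (named list of
#'   \linkS4class{DensityVolume}), \code{truth} (per-sample ground-truth
#'   data.frame), \code{layout} (landmark slice and section sizes) and
#'   \code{params}.
#' @export
makeStudy <- function(groupSizes = c(CTR = 5L, CIA_PBS = 5L,
                                     CIA_SclAbI = 5L),
                      thinningFactor = 0.8, marrowFoldChange = 1.6,
                      pitDensity = 5, pitRadius = 0.03,
                      lateral = 128L,
                      sections = c(joint = 100L, metaphysis = 100L,
                                   diaphysis = 100L),
                      outerRadius = 0.30, innerRadius = 0.24,
                      rodDiameter = 0.06, rodSpacing = 0.12,
                      boneDensity = 900, backgroundDensity = 100,
                      noiseSd = 60, voxelSize = 6, seed = 1L) {
  if (any(groupSizes < 1)) stop("group sizes must be >= 1")
  if (thinningFactor <= 0) stop("non-physical thinning factor")
  if (marrowFoldChange <= 0) stop("non-physical marrow fold-change")
  groups <- rep(names(groupSizes), groupSizes)
  nTot <- length(groups)
  rShaftApp <- innerRadius / sqrt(marrowFoldChange)
  if (rShaftApp <= rodDiameter)
    stop("endosteal apposition produces a non-physical inner radius")

  volumes <- vector("list", nTot)
  truth <- NULL
  vox <- voxelSize / 1000
  for (i in seq_len(nTot)) {
    grp <- groups[i]
    sid <- sprintf("%s_%02d", grp, sum(groups[seq_len(i)] == grp))
    sseed <- as.integer((as.numeric(seed) * 1000003 + i * 7919) %%
                          .Machine$integer.max)
    rodD <- if (grp == "CIA_PBS") rodDiameter * thinningFactor
            else rodDiameter
    rShaft <- if (grp == "CIA_SclAbI") rShaftApp else innerRadius
    pd <- if (grp == "CTR") 0 else pitDensity
    ph <- .tibiaPhantom(lateral = lateral, sections = sections,
                        outerRadius = outerRadius,
                        innerRadius = innerRadius,
                        innerRadiusShaft = rShaft,
                        rodDiameter = rodD, rodSpacing = rodSpacing,
                        pitDensity = pd, pitRadius = pitRadius,
                        boneDensity = boneDensity,
                        backgroundDensity = backgroundDensity,
                        noiseSd = noiseSd, voxelSize = voxelSize,
                        seed = sseed)
    ph$volume@name <- sid
    volumes[[i]] <- ph$volume
    truth <- rbind(truth, data.frame(
      sample = sid, group = grp, seed = sseed,
      rod_diameter_mm = rodD, thinning_factor = rodD / rodDiameter,
      inner_radius_shaft_mm = rShaft,
      marrow_volume_mm3 = pi * rShaft^2 *
        (sections[["diaphysis"]] * vox),
      pit_density = pd, pit_count = ph$pit_count,
      outer_radius_mm = outerRadius, inner_radius_mm = innerRadius))
  }
  names(volumes) <- truth$sample
  list(volumes = volumes, truth = truth,
       layout = list(landmark = sections[["joint"]] + 1L,
                     sections = sections, lateral = lateral),
       params = list(thinningFactor = thinningFactor,
                     marrowFoldChange = marrowFoldChange,
                     pitDensity = pitDensity, pitRadius = pitRadius,
                     outerRadius = outerRadius,
                     innerRadius = innerRadius,
                     rodDiameter = rodDiameter, rodSpacing = rodSpacing,
                     boneDensity = boneDensity,
                     backgroundDensity = backgroundDensity,
                     noiseSd = noiseSd, voxelSize = voxelSize,
                     seed = seed))
}

#' Write a generated study to disk
#'
#' Writes every volume, the ground-truth table (\code{truth.csv}) and a
#' ready-to-run pipeline manifest (\code{run.yaml}) with the standard ROI
#' definitions for the composite phantom layout.
#'
#' @param study result of [makeStudy()].
#' @param dir output directory (created if needed).
#' @param format volume format extension: "mha", "mhd", "nrrd" or "tif".
#' @return Invisibly, the manifest path.
#' @export
writeStudy <- function(study, dir, format = "mha") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  vox <- study$params$voxelSize / 1000
  lay <- study$layout
  nj <- lay$sections[["joint"]]; nm <- lay$sections[["metaphysis"]]
  nd <- lay$sections[["diaphysis"]]
  landmark <- lay$landmark
  # metaphyseal trabecular slab: 0.30 mm past the growth plate (or a third
  # of the segment for short phantoms); midshaft slab: centred in the
  # diaphysis
  metaOff <- min(0.30, floor(nm / 3) * vox)
  metaExt <- max(1, (nm - .roundHalfAway(metaOff / vox) - 10)) * vox
  shaftOff <- (nm + floor(nd / 4)) * vox
  shaftExt <- floor(nd / 2) * vox
  rois <- list(
    list(label = "ankle_joint", type = "joint",
         center_slice = floor(nj / 2), n_slices = nj - 10L,
         measure = "erosion"),
    list(label = "tibial_metaphysis_trab", type = "slab",
         landmark_slice = landmark, offset_mm = metaOff,
         extent_mm = metaExt, direction = 1L, measure = "trabecular"),
    list(label = "tibial_midshaft_cort", type = "slab",
         landmark_slice = landmark, offset_mm = shaftOff,
         extent_mm = shaftExt, direction = 1L, measure = "cortical"))
  samples <- vector("list", length(study$volumes))
  for (i in seq_along(study$volumes)) {
    v <- study$volumes[[i]]
    fn <- paste0(volName(v), ".", format)
    writeVolume(v, file.path(dir, fn))
    samples[[i]] <- list(id = volName(v),
                         group = study$truth$group[i],
                         volume = fn, rois = rois)
  }
  write.csv(study$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  config <- list(
    seed = study$params$seed,
    output_dir = "results",
    filter = list(sigma = 0.8, support = 1L),
    strong_filter = list(sigma = 2.5, support = 5L),
    segment = list(threshold = 500),
    samples = samples)
  manifest <- file.path(dir, "run.yaml")
  yaml::write_yaml(config, manifest)
  invisible(manifest)
}

#' Measurement-level null draws for calibration
#'
#' Draws per-sample measurement values for a null study (all groups
#' exchangeable) directly at the measurement level: under null effect
#' parameters the generator's groups differ only by noise, so the sampling
#' distribution of any morphometric readout is a common distribution
#' across groups, here taken normal.
#'
#' @param nPerGroup samples per group.
#' @param groups group labels.
#' @param mean,sd common measurement distribution.
#' @param measurement measurement name.
#' @return A group table data.frame (\code{sample}, \code{group},
#'   \code{measurement}, \code{value}).
#' @export
nullMeasurementTable <- function(nPerGroup = 10,
                                 groups = c("CTR", "CIA_PBS",
                                            "CIA_SclAbI"),
                                 mean = 0.2, sd = 0.03,
                                 measurement = "BVTV") {
  g <- rep(groups, each = nPerGroup)
  data.frame(sample = sprintf("s%02d", seq_along(g)), group = g,
             measurement = measurement,
             value = rnorm(length(g), mean, sd))
}
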