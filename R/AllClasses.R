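#' Calibrated 3D mineral-density volume
#'
#' Holds a reconstructed microCT volume on the calibrated hydroxyapatite
#' density scale (mg HA/cm^3) together with its isotropic voxel size.
#' The tomogram stack runs along the first array dimension: element
#' \code{data[k, , ]} is tomogram (slice) \code{k}.
#'
#' @slot data 3D numeric array of densities, mg HA/cm^3.
#' @slot voxelSize isotropic voxel edge length, micrometres.
#' @slot sliceAxis array axis carrying the tomogram stack (always 1).
#' @slot name free-text identifier.
#' @export
setClass("DensityVolume",
  representation(data = "array", voxelSize = "numeric",
                 sliceAxis = "integer", name = "character"),
  prototype(sliceAxis = 1L, name = ""))

setValidity("DensityVolume", function(object) {
  d <- object@data
  if (length(dim(d)) != 3L) return("data must be a 3D array")
  if (any(dim(d) < 1L)) return("all three dimensions must be >= 1")
  if (!is.numeric(d)) return("data must be numeric")
  if (anyNA(d) || any(!is.finite(d))) return("density values must be finite")
  vs <- object@voxelSize
  if (length(vs) != 1L || !is.finite(vs) || vs <= 0)
    return("voxelSize must be a single positive number (isotropic, um)")
  if (!identical(object@sliceAxis, 1L))
    return("sliceAxis must be 1 (tomogram stack along the first axis)")
  TRUE
})

#' Binary segmentation volume
#'
#' A boolean mask sharing the geometry of the \linkS4class{DensityVolume}
#' it was derived from (TRUE = bone).
#'
#' @slot data 3D logical array.
#' @slot voxelSize isotropic voxel edge length, micrometres.
#' @slot sliceAxis array axis carrying the tomogram stack (always 1).
#' @slot name free-text identifier.
#' @export
setClass("BinaryVolume",
  representation(data = "array", voxelSize = "numeric",
                 sliceAxis = "integer", name = "character"),
  prototype(sliceAxis = 1L, name = ""))

setValidity("BinaryVolume", function(object) {
  d <- object@data
  if (length(dim(d)) != 3L) return("data must be a 3D array")
  if (!is.logical(d)) return("mask values must be strictly binary (logical)")
  if (anyNA(d)) return("mask must not contain NA")
  vs <- object@voxelSize
  if (length(vs) != 1L || !is.finite(vs) || vs <= 0)
    return("voxelSize must be a single positive number (isotropic, um)")
  if (!identical(object@sliceAxis, 1L))
    return("sliceAxis must be 1 (tomogram stack along the first axis)")
  TRUE
})

.roiLabels <- c("vertebral_body", "tibial_metaphysis_trab",
                "tibial_midshaft_cort", "knee_joint", "ankle_joint", "custom")

#' Region-of-interest mask
#'
#' A \linkS4class{BinaryVolume} restricted to the region analysed, carrying
#' an anatomical label.
#'
#' @slot label one of \code{vertebral_body}, \code{tibial_metaphysis_trab},
#'   \code{tibial_midshaft_cort}, \code{knee_joint}, \code{ankle_joint},
#'   \code{custom}.
#' @export
setClass("RoiMask", contains = "BinaryVolume",
         representation(label = "character"),
         prototype(label = "custom"))

setValidity("RoiMask", function(object) {
  if (length(object@label) != 1L || !(object@label %in% .roiLabels))
    return(paste("label must be one of:", paste(.roiLabels, collapse = ", ")))
  TRUE
})

#' Gaussian filter parameters
#'
#' Standard deviation and truncation half-width (support) of the sampled,
#' renormalised Gaussian kernel, both in voxel units. \code{support = 1}
#' gives a 3-tap kernel per axis; \code{sigma = 0} is the identity.
#'
#' @slot sigma Gaussian standard deviation, voxels (>= 0).
#' @slot support kernel truncation half-width, voxels (integer >= 0).
#' @export
setClass("FilterParams",
  representation(sigma = "numeric", support = "integer"))

setValidity("FilterParams", function(object) {
  if (length(object@sigma) != 1L || !is.finite(object@sigma) ||
      object@sigma < 0)
    return("sigma must be a single non-negative number")
  if (length(object@support) != 1L || is.na(object@support) ||
      object@support < 0L)
    return("support must be a single non-negative integer")
  TRUE
})

#' Segmentation parameters
#'
#' @slot threshold fixed segmentation threshold, mg HA/cm^3; voxels with
#'   density >= threshold are classified as bone.
#' @export
setClass("SegmentationParams", representation(threshold = "numeric"))

setValidity("SegmentationParams", function(object) {
  if (length(object@threshold) != 1L || !is.finite(object@threshold))
    return("threshold must be a single finite number")
  TRUE
})

.phantomFamilies <- c("sphere", "plate", "rod_lattice", "cortical_tube",
                      "pitted_sphere", "pitted_tube", "speckle")

#' Synthetic phantom specification
#'
#' Parameters of one synthetic calibrated volume: an analytic solid
#' voxelised at voxel centres, mapped to bone/background densities, with
#' independent Gaussian scanner noise added everywhere.
#'
#' @slot family phantom family; one of \code{sphere}, \code{plate},
#'   \code{rod_lattice}, \code{cortical_tube}, \code{pitted_sphere},
#'   \code{pitted_tube}, \code{speckle}.
#' @slot geometry named numeric list of family-specific lengths in mm
#'   (e.g. \code{radius}, \code{thickness}, \code{rod_diameter},
#'   \code{spacing}, \code{outer_radius}, \code{inner_radius}); for
#'   \code{speckle}, \code{bone_probability}.
#' @slot gridDim integer grid dimensions (slices, rows, columns).
#' @slot boneDensity,backgroundDensity densities, mg HA/cm^3.
#' @slot noiseSd additive Gaussian noise standard deviation, mg HA/cm^3.
#' @slot pitDensity pits per mm^2 of analytic surface (pitted families).
#' @slot pitRadius hemispherical pit radius, mm.
#' @slot voxelSize voxel size, micrometres.
#' @slot seed integer RNG seed.
#' @export
setClass("PhantomSpec",
  representation(family = "character", geometry = "list",
                 gridDim = "integer", boneDensity = "numeric",
                 backgroundDensity = "numeric", noiseSd = "numeric",
                 pitDensity = "numeric", pitRadius = "numeric",
                 voxelSize = "numeric", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  if (!(object@family %in% .phantomFamilies))
    return(paste("family must be one of:",
                 paste(.phantomFamilies, collapse = ", ")))
  if (length(object@gridDim) != 3L || any(object@gridDim < 1L))
    return("gridDim must be three positive integers")
  g <- object@geometry
  if (length(g) && (is.null(names(g)) || any(!nzchar(names(g)))))
    return("geometry entries must be named")
  lens <- unlist(g[setdiff(names(g), "bone_probability")])
  if (length(lens) && any(!is.finite(lens) | lens <= 0))
    return("geometric lengths must be positive and finite")
  if (object@voxelSize <= 0) return("voxelSize must be positive")
  if (object@noiseSd < 0) return("noiseSd must be non-negative")
  if (object@pitDensity < 0 || object@pitRadius < 0)
    return("pit parameters must be non-negative")
  if (!(object@boneDensity > object@backgroundDensity))
    return("boneDensity must exceed backgroundDensity")
  TRUE
})

#' Group-comparison result
#'
#' Result of a group comparison: the omnibus test with its statistic and
#' p-value, plus (for Tukey's post hoc test) one adjusted p-value per group
#' pair with a significance flag at \code{alpha}.
#'
#' @slot test test name.
#' @slot statistic test statistic value.
#' @slot pValue omnibus p-value.
#' @slot pairwise data.frame of pairwise comparisons (columns
#'   \code{groupA}, \code{groupB}, \code{diff}, \code{pAdj},
#'   \code{significant}); empty for two-sample tests.
#' @slot alpha significance level.
#' @export
setClass("StatsResult",
  representation(test = "character", statistic = "numeric",
                 pValue = "numeric", pairwise = "data.frame",
                 alpha = "numeric"))

setValidity("StatsResult", function(object) {
  if (!is.na(object@pValue) &&
      (object@pValue < 0 || object@pValue > 1))
    return("pValue must lie in [0, 1]")
  if (nrow(object@pairwise) &&
      any(object@pairwise$pAdj < 0 | object@pairwise$pAdj > 1, na.rm = TRUE))
    return("adjusted p-values must lie in [0, 1]")
  TRUE
})
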