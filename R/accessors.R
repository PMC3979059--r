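#' Construct a DensityVolume
#'
#' @param data 3D numeric array, densities in mg HA/cm^3; slice k is
#'   \code{data[k, , ]}.
#' @param voxelSize isotropic voxel size, micrometres.
#' @param name optional identifier.
#' @return A \linkS4class{DensityVolume}.
#' @examples
#' v <- DensityVolume(array(100, c(4, 4, 4)), voxelSize = 6)
#' voxelSize(v)
#' @export
DensityVolume <- function(data, voxelSize, name = "") {
  if (is.logical(data)) storage.mode(data) <- "double"
  new("DensityVolume", data = data, voxelSize = as.numeric(voxelSize),
      sliceAxis = 1L, name = as.character(name))
}

#' Construct a BinaryVolume
#'
#' @param data 3D logical array (TRUE = bone).
#' @param voxelSize isotropic voxel size, micrometres.
#' @param name optional identifier.
#' @return A \linkS4class{BinaryVolume}.
#' @export
BinaryVolume <- function(data, voxelSize, name = "") {
  if (is.numeric(data)) {
    if (!all(data %in% c(0, 1)))
      stop("mask values must be strictly binary")
    data <- array(data != 0, dim(data))
  }
  new("BinaryVolume", data = data, voxelSize = as.numeric(voxelSize),
      sliceAxis = 1L, name = as.character(name))
}

#' Construct an RoiMask
#'
#' @param data 3D logical array selecting the region analysed.
#' @param voxelSize isotropic voxel size, micrometres.
#' @param label anatomical label.
#' @param name optional identifier.
#' @return An \linkS4class{RoiMask}.
#' @export
RoiMask <- function(data, voxelSize, label = "custom", name = "") {
  new("RoiMask", data = data, voxelSize = as.numeric(voxelSize),
      sliceAxis = 1L, name = as.character(name), label = label)
}

#' Filter parameter constructor
#'
#' @param sigma Gaussian standard deviation, voxels.
#' @param support kernel truncation half-width, voxels.
#' @return A \linkS4class{FilterParams}.
#' @examples
#' filterParams(0.8, 1)  # the standard noise filter
#' filterParams(2.5, 5)  # the strong smoothing filter
#' @export
filterParams <- function(sigma, support) {
  new("FilterParams", sigma = as.numeric(sigma),
      support = as.integer(support))
}

#' Segmentation parameter constructor
#'
#' @param threshold fixed density threshold, mg HA/cm^3 (default 500).
#' @return A \linkS4class{SegmentationParams}.
#' @export
segmentationParams <- function(threshold = 500) {
  new("SegmentationParams", threshold = as.numeric(threshold))
}

#' @describeIn DensityVolume-class voxel size in micrometres.
#' @param x a volume object.
#' @export
setMethod("voxelSize", "DensityVolume", function(x) x@voxelSize)

#' @export
setMethod("voxelSize", "BinaryVolume", function(x) x@voxelSize)

#' @describeIn DensityVolume-class the underlying 3D array.
#' @export
setMethod("volData", "DensityVolume", function(x) x@data)

#' @export
setMethod("volData", "BinaryVolume", function(x) x@data)

#' @export
setMethod("sliceAxis", "DensityVolume", function(x) x@sliceAxis)

#' @export
setMethod("sliceAxis", "BinaryVolume", function(x) x@sliceAxis)

#' @export
setMethod("volName", "DensityVolume", function(x) x@name)

#' @export
setMethod("volName", "BinaryVolume", function(x) x@name)

#' @describeIn RoiMask-class the anatomical label.
#' @param x an RoiMask.
#' @export
setMethod("roiLabel", "RoiMask", function(x) x@label)

#' @export
setMethod("dim", "DensityVolume", function(x) dim(x@data))

#' @export
setMethod("dim", "BinaryVolume", function(x) dim(x@data))

setMethod("show", "DensityVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "DensityVolume '%s': %d x %d x %d voxels @ %g um (slices along axis 1)\n",
    object@name, d[1], d[2], d[3], object@voxelSize))
  cat(sprintf("  density range: [%.1f, %.1f] mg HA/cm^3\n",
              min(object@data), max(object@data)))
})

setMethod("show", "BinaryVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("%s '%s': %d x %d x %d voxels @ %g um, %d foreground voxels\n",
              class(object), object@name, d[1], d[2], d[3],
              object@voxelSize, sum(object@data)))
  if (is(object, "RoiMask"))
    cat(sprintf("  label: %s\n", object@label))
})

setMethod("show", "StatsResult", function(object) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (alpha = %g)\n",
              object@test, object@statistic, object@pValue, object@alpha))
  if (nrow(object@pairwise)) {
    cat("Pairwise comparisons (Tukey-adjusted):\n")
    print(object@pairwise, row.names = FALSE)
  }
})

# shared geometry check used across modules
.checkSameGeometry <- function(a, b) {
  if (!identical(dim(a@data), dim(b@data)))
    stop("geometry mismatch: volumes have different dimensions")
  if (abs(a@voxelSize - b@voxelSize) > 1e-9 * a@voxelSize)
    stop("geometry mismatch: volumes have different voxel sizes")
  invisible(TRUE)
}

# voxel edge in mm
.voxMm <- function(x) voxelSize(x) / 1000
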