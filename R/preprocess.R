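## Noise filtering and segmentation.
##
## The Gaussian filter is the separable sampled kernel truncated at
## +/- `support` voxels per axis and renormalised to sum 1 (so constants
## are preserved exactly), with mirror-reflected boundary handling to avoid
## darkening at volume edges. The standard noise filter is sigma 0.8,
## support 1; the strong smoothing filter used by the erosion module is
## sigma 2.5, support 5. Segmentation is a fixed inclusive threshold on
## the calibrated density scale: bone is density >= threshold, with the
## conventional threshold at 500 mg HA/cm^3.

#' @describeIn gaussianFilter Filter a density volume.
#' @param vol a \linkS4class{DensityVolume}.
#' @param params a \linkS4class{FilterParams}; \code{sigma = 0} or
#'   \code{support = 0} yields the identity.
#' @param ... unused.
#' @return A new \linkS4class{DensityVolume} with identical geometry.
#' @examples
#' v <- DensityVolume(array(500, c(8, 8, 8)), 6)
#' f <- gaussianFilter(v, filterParams(0.8, 1))
#' stopifnot(all(volData(f) == 500))  # constants preserved
#' @export
setMethod("gaussianFilter", signature("DensityVolume", "FilterParams"),
  function(vol, params, ...) {
    arr <- volData(vol)
    out <- .gaussianFilterCpp(as.vector(arr), dim(arr),
                              params@sigma, params@support)
    DensityVolume(array(out, dim(arr)), voxelSize(vol),
                  name = volName(vol))
  })

#' @export
setMethod("gaussianFilter", signature("DensityVolume", "numeric"),
  function(vol, params, support = 1L, ...) {
    gaussianFilter(vol, filterParams(params, support))
  })

#' @describeIn segmentBone Fixed-threshold segmentation (bone where
#'   density >= threshold).
#' @param vol a \linkS4class{DensityVolume} (normally the standard-filtered
#'   volume).
#' @param params a \linkS4class{SegmentationParams}.
#' @param ... unused.
#' @return A \linkS4class{BinaryVolume} sharing the volume's geometry.
#' @export
setMethod("segmentBone", signature("DensityVolume", "SegmentationParams"),
  function(vol, params, ...) {
    arr <- volData(vol)
    BinaryVolume(array(arr >= params@threshold, dim(arr)),
                 voxelSize(vol), name = volName(vol))
  })

#' @export
setMethod("segmentBone", signature("DensityVolume", "numeric"),
  function(vol, params, ...) {
    segmentBone(vol, segmentationParams(params))
  })
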