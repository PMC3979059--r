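## Focal-erosion surface statistics.
##
## Two independent markers of periarticular focal erosion:
##   * surface density BS/BV, which rises with superficial pitting and
##     falls with bone accrual (it depends on bone volume), and
##   * the smoothness estimator BSsmooth/BS, the ratio of the bone surface
##     recomputed after a strong Gaussian smoothing of the raw grayscale
##     volume (sigma 2.5, support 5) to the original bone surface from the
##     standard filter (sigma 0.8, support 1), both meshed at the same
##     fixed threshold over the same ROI. Additional smoothing leaves a
##     smooth surface unchanged (ratio near 1) but erases the excess area
##     of a rough, pitted surface (ratio toward 0), independently of bone
##     volume changes.
##
## The strong filter is applied to the raw volume, not on top of the
## standard filter; smoothing the binary mask instead is available via
## `onMask = TRUE` but is not the default.

#' Surface density BS/BV
#'
#' @param BS bone surface, mm^2.
#' @param BV bone volume, mm^3 (> 0).
#' @return BS/BV in 1/mm.
#' @examples
#' surfaceDensity(2, 1)  # 2 mm^-1
#' @export
surfaceDensity <- function(BS, BV) {
  if (any(BV <= 0)) stop("BV must be positive")
  BS / BV
}

#' Smoothness estimator BSsmooth/BS and companion erosion scores
#'
#' Computes BS and BV from the standard-filtered volume segmented at the
#' fixed threshold, recomputes the surface (BSsmooth) identically from the
#' strongly smoothed volume, and returns the erosion scores including
#' \code{smoothness = BSsmooth / BS}. If the strong filter erases all
#' iso-surface, \code{BSsmooth = 0} and \code{smoothness = 0} (the
#' extremely-rough limit).
#'
#' @param raw the unsmoothed calibrated \linkS4class{DensityVolume}.
#' @param roi \linkS4class{RoiMask} (default: whole volume).
#' @param standard \linkS4class{FilterParams} of the noise filter
#'   (default sigma 0.8, support 1).
#' @param strong \linkS4class{FilterParams} of the strong smoothing filter
#'   (default sigma 2.5, support 5).
#' @param seg \linkS4class{SegmentationParams} (default threshold 500).
#' @param onMask apply the strong filter to the binary segmentation
#'   (rescaled to the density range) instead of the raw grayscale volume.
#' @return One-row data.frame: \code{label}, \code{BS}, \code{BV},
#'   \code{BS_over_BV}, \code{BS_smooth}, \code{smoothness}, plus the
#'   parameter set used.
#' @export
smoothnessEstimator <- function(raw, roi = NULL,
                                standard = filterParams(0.8, 1),
                                strong = filterParams(2.5, 5),
                                seg = segmentationParams(500),
                                onMask = FALSE) {
  if (is.null(roi))
    roi <- RoiMask(array(TRUE, dim(raw)), voxelSize(raw),
                   label = "custom", name = volName(raw))
  fstd <- gaussianFilter(raw, standard)
  mask <- segmentBone(fstd, seg)
  BS <- boneSurface(fstd, seg@threshold, roi)
  if (BS == 0)
    stop("no bone surface in the ROI under standard filtering")
  BV <- boneVolume(mask, roi)
  strongInput <- if (onMask) {
    lo <- min(volData(raw)); hi <- max(volData(raw))
    DensityVolume(array(ifelse(volData(mask), hi, lo), dim(raw)),
                  voxelSize(raw), name = volName(raw))
  } else raw
  fsm <- gaussianFilter(strongInput, strong)
  BSsm <- boneSurface(fsm, seg@threshold, roi)
  data.frame(label = roiLabel(roi), BS = BS, BV = BV,
             BS_over_BV = surfaceDensity(BS, BV), BS_smooth = BSsm,
             smoothness = if (BSsm == 0) 0 else BSsm / BS,
             sigma_standard = standard@sigma,
             support_standard = standard@support,
             sigma_strong = strong@sigma, support_strong = strong@support,
             threshold = seg@threshold)
}
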