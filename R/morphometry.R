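## Three-dimensional morphometry.
##
## Volumes (BV, TV, marrow) are voxel counts times the voxel volume, so
## conservation identities hold exactly. The bone surface BS is the area
## of the triangulated iso-surface of the *filtered grayscale* density
## field at the segmentation threshold (voxel-face counting overestimates
## smooth surfaces badly); sheets cut open at the ROI boundary contribute
## nothing. Thickness (Tb.Th, Ct.Th) is the model-independent direct
## method: at each bone voxel, the diameter of the largest sphere fully
## inscribed in the structure that contains the voxel, averaged per-voxel
## (volume-weighted) over the ROI.

.asMaskArray <- function(x) {
  if (is(x, "BinaryVolume")) volData(x) else x
}

#' Bone volume within an ROI
#'
#' @param mask segmented bone, a \linkS4class{BinaryVolume}.
#' @param roi an \linkS4class{RoiMask} sharing the mask's geometry.
#' @return Bone volume in mm^3.
#' @export
boneVolume <- function(mask, roi) {
  .checkSameGeometry(mask, roi)
  sum(volData(mask) & volData(roi)) * .voxMm(mask)^3
}

#' Total (ROI) volume
#'
#' @param roi a non-empty \linkS4class{RoiMask}.
#' @return ROI volume in mm^3.
#' @export
totalVolume <- function(roi) {
  n <- sum(volData(roi))
  if (n == 0) stop("ROI is empty")
  n * .voxMm(roi)^3
}

#' Bone surface area within an ROI
#'
#' Area of the triangulated iso-surface of the filtered density field at
#' the segmentation threshold, restricted to grid cells lying fully inside
#' the ROI (so surface sheets clipped at the ROI boundary are left open
#' and their cut ends are not counted).
#'
#' @param filtered the standard-filtered \linkS4class{DensityVolume}.
#' @param threshold iso-value, mg HA/cm^3 (the segmentation threshold).
#' @param roi optional \linkS4class{RoiMask}; default whole volume.
#' @return Surface area in mm^2 (0 when the ROI contains no iso-surface).
#' @export
boneSurface <- function(filtered, threshold = 500, roi = NULL) {
  arr <- volData(filtered)
  roiVec <- NULL
  if (!is.null(roi)) {
    .checkSameGeometry(filtered, roi)
    roiVec <- as.vector(volData(roi))
  }
  a <- .isoSurfaceAreaCpp(as.vector(arr), dim(arr), threshold, roiVec)
  a * .voxMm(filtered)^2
}

#' Local thickness map
#'
#' Model-independent local thickness: for every foreground voxel, the
#' diameter of the largest inscribed sphere containing it, from the exact
#' Euclidean distance transform with redundant-sphere pruning.
#'
#' @param mask a \linkS4class{BinaryVolume}.
#' @return 3D numeric array of thickness in mm (0 outside the structure).
#' @export
localThickness <- function(mask) {
  arr <- .asMaskArray(mask)
  th <- .localThicknessCpp(as.vector(arr), dim(arr))
  array(th * .voxMm(mask), dim(arr))
}

.meanThickness <- function(mask, roi) {
  .checkSameGeometry(mask, roi)
  th <- localThickness(mask)
  sel <- volData(mask) & volData(roi)
  if (!any(sel)) stop("no bone voxels inside the ROI")
  mean(th[sel])
}

#' Mean trabecular thickness (Tb.Th)
#'
#' Volume-weighted mean of the local thickness over bone voxels in the
#' ROI. The thickness field is computed on the full mask so structures
#' extending beyond the ROI are measured at their true thickness.
#'
#' @param mask segmented bone, a \linkS4class{BinaryVolume}.
#' @param roi \linkS4class{RoiMask} over which to average.
#' @return Tb.Th in mm.
#' @export
trabecularThickness <- function(mask, roi) .meanThickness(mask, roi)

#' Mean cortical thickness (Ct.Th)
#'
#' Same direct-method thickness as [trabecularThickness()], applied to the
#' cortical shell within a mid-diaphyseal slab.
#'
#' @param cortex cortical shell, a \linkS4class{BinaryVolume}.
#' @param slab \linkS4class{RoiMask} selecting the slab.
#' @return Ct.Th in mm.
#' @export
corticalThickness <- function(cortex, slab) .meanThickness(cortex, slab)

#' Marrow and total diaphysis volume
#'
#' The marrow volume is the interior enclosed by the cortical shell
#' (per-slice filling minus the shell); the total diaphysis volume is the
#' shell plus the marrow, so \code{total = marrow + cortical BV} holds
#' exactly.
#'
#' @param cortex cortical shell, a \linkS4class{BinaryVolume}.
#' @param slab \linkS4class{RoiMask} selecting the slab.
#' @return Named numeric: \code{marrow}, \code{total} (mm^3).
#' @export
marrowAndTotalVolume <- function(cortex, slab) {
  .checkSameGeometry(cortex, slab)
  slices <- which(apply(volData(slab), 1, any))
  interior <- trabecularMask(cortex, slices = slices)
  v3 <- .voxMm(cortex)^3
  marrow <- sum(volData(interior) & volData(slab)) * v3
  shell <- sum(volData(cortex) & volData(slab)) * v3
  c(marrow = marrow, total = marrow + shell)
}

#' Full morphometry record for one ROI
#'
#' Convenience wrapper returning the standard parameter set as a one-row
#' data.frame: BV, TV, BV/TV, BS and (depending on \code{kind}) Tb.Th or
#' Ct.Th with marrow and total diaphysis volume.
#'
#' @param filtered standard-filtered \linkS4class{DensityVolume}.
#' @param mask segmented bone (from the same filtered volume).
#' @param roi \linkS4class{RoiMask} to analyse.
#' @param threshold segmentation threshold, mg HA/cm^3.
#' @param kind "trabecular" (Tb.Th over bone in the ROI), "cortical"
#'   (cortical shell extraction, Ct.Th, marrow and total volume), or
#'   "joint" (volumes and surface only).
#' @return One-row data.frame.
#' @export
morphometry <- function(filtered, mask, roi, threshold = 500,
                        kind = c("trabecular", "cortical", "joint")) {
  kind <- match.arg(kind)
  BV <- boneVolume(mask, roi)
  TV <- totalVolume(roi)
  BS <- boneSurface(filtered, threshold, roi)
  out <- data.frame(label = roiLabel(roi), BV = BV, TV = TV,
                    BVTV = BV / TV, BS = BS, TbTh = NA_real_,
                    CtTh = NA_real_, marrow_volume = NA_real_,
                    total_diaphysis_volume = NA_real_)
  if (kind == "trabecular") {
    out$TbTh <- trabecularThickness(mask, roi)
  } else if (kind == "cortical") {
    cortex <- cortexMask(.maskWithin(mask, roi))
    out$CtTh <- corticalThickness(cortex, roi)
    mt <- marrowAndTotalVolume(cortex, roi)
    out$marrow_volume <- mt[["marrow"]]
    out$total_diaphysis_volume <- mt[["total"]]
  }
  out
}

# restrict a bone mask to an ROI (outside voxels cleared)
.maskWithin <- function(mask, roi) {
  BinaryVolume(volData(mask) & volData(roi), voxelSize(mask),
               name = volName(mask))
}
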