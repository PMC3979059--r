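## Region-of-interest construction.
##
## ROIs follow the conventions of murine tibial microCT protocols: slabs
## are contiguous runs of tomograms along the slice axis, specified either
## relative to an anatomic landmark (growth plate) with a signed offset, or
## centred on a slice (synovial space). Slices are 1-based; a slab of n
## slices starting at s covers s, ..., s + n - 1. Millimetre extents are
## converted to slice counts by rounding half away from zero, so at 6 um
## a 0.6 mm slab is exactly 100 tomograms and a 1.2 mm slab exactly 200.

# round half away from zero (base round() is half-to-even)
.roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Convert a landmark-anchored slab specification to a slice range
#'
#' The slab starts \code{direction * offsetMm} from the landmark slice and
#' extends \code{extentMm} toward increasing slice index:
#' \code{n = round(extentMm * 1000 / voxelSize)} slices (half away from
#' zero), \code{start = landmarkSlice + direction * round(offsetMm * 1000
#' / voxelSize)}.
#'
#' @param landmarkSlice 1-based slice index of the anatomic landmark.
#' @param offsetMm distance from landmark to slab start, mm (signed).
#' @param extentMm slab length, mm (> 0).
#' @param voxelSize voxel size, micrometres.
#' @param direction +1 or -1: side of the landmark on which the slab starts.
#' @param nSlices optional total slice count of the volume; when given,
#'   ranges leaving the volume are an error.
#' @return Integer vector \code{c(start, end)} (1-based, inclusive);
#'   attribute \code{n} carries the slice count.
#' @examples
#' slabToSlices(1, 0, 1.2, 6)[2]  # 1.2 mm at 6 um -> 200 tomograms
#' @export
slabToSlices <- function(landmarkSlice, offsetMm, extentMm, voxelSize,
                         direction = 1L, nSlices = NULL) {
  stopifnot(length(landmarkSlice) == 1L, length(extentMm) == 1L)
  if (!direction %in% c(-1, 1)) stop("direction must be +1 or -1")
  if (extentMm <= 0) stop("extentMm must be positive")
  n <- .roundHalfAway(extentMm * 1000 / voxelSize)
  if (n < 1) stop("slab extent rounds to zero slices")
  start <- landmarkSlice + direction * .roundHalfAway(offsetMm * 1000 / voxelSize)
  end <- start + n - 1
  if (!is.null(nSlices) && (start < 1 || end > nSlices))
    stop(sprintf("slab [%d, %d] exits the volume (1..%d)", start, end,
                 nSlices))
  structure(c(start = as.integer(start), end = as.integer(end)),
            n = as.integer(n))
}

.slabMask <- function(vol, start, end, lateralMask = NULL) {
  d <- dim(vol)
  m <- array(FALSE, d)
  if (is.null(lateralMask)) {
    m[start:end, , ] <- TRUE
  } else {
    if (is.matrix(lateralMask)) {
      if (!identical(dim(lateralMask), d[2:3]))
        stop("lateral mask does not match the in-plane dimensions")
      for (k in start:end) m[k, , ] <- lateralMask
    } else {
      if (!identical(dim(lateralMask), d))
        stop("lateral mask does not match the volume dimensions")
      m[start:end, , ] <- lateralMask[start:end, , ]
    }
  }
  m
}

#' Landmark-anchored slab ROI
#'
#' Builds an \linkS4class{RoiMask} covering the full lateral field of view
#' over the slice range given by [slabToSlices()].
#'
#' @inheritParams slabToSlices
#' @param vol the volume the ROI applies to.
#' @param label anatomical label for the ROI.
#' @return An \linkS4class{RoiMask}.
#' @export
slabRoi <- function(vol, landmarkSlice, offsetMm, extentMm,
                    direction = 1L, label = "custom") {
  r <- slabToSlices(landmarkSlice, offsetMm, extentMm, voxelSize(vol),
                    direction, nSlices = dim(vol)[1])
  RoiMask(.slabMask(vol, r[1], r[2]), voxelSize(vol), label = label,
          name = volName(vol))
}

#' Centred joint ROI
#'
#' A slab of \code{nSlices} tomograms centred at \code{centerSlice} (ties
#' broken toward the lower index for even counts), optionally intersected
#' with a lateral mask, as used for periarticular erosion scoring over the
#' knee (640 tomograms) or ankle (700 tomograms).
#'
#' @param vol the volume the ROI applies to.
#' @param centerSlice 1-based central slice.
#' @param nSlices number of tomograms (>= 1).
#' @param lateralMask optional 2D in-plane mask (rows x columns) or 3D
#'   logical array to intersect with the slab.
#' @param label anatomical label.
#' @return An \linkS4class{RoiMask}.
#' @export
jointRoi <- function(vol, centerSlice, nSlices, lateralMask = NULL,
                     label = "custom") {
  stopifnot(nSlices >= 1)
  start <- centerSlice - floor(nSlices / 2)
  end <- start + nSlices - 1
  if (start < 1 || end > dim(vol)[1])
    stop(sprintf("joint slab [%d, %d] exceeds volume bounds (1..%d)",
                 start, end, dim(vol)[1]))
  RoiMask(.slabMask(vol, start, end, lateralMask), voxelSize(vol),
          label = label, name = volName(vol))
}

## ---- cortical shell / trabecular compartment -----------------------------

.regionCodes <- function(mask) {
  arr <- volData(mask)
  array(.sliceRegionCodesCpp(as.vector(arr), dim(arr)), dim(arr))
}

# 3x3 box (8-neighbour) binary dilation of one 2D slice
.dilate2d <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  a <- m
  a[-1, ] <- a[-1, ] | m[-nr, ]
  a[-nr, ] <- a[-nr, ] | m[-1, ]
  b <- a
  b[, -1] <- b[, -1] | a[, -nc]
  b[, -nc] <- b[, -nc] | a[, -1]
  b
}

#' Extract the cortical shell from a bone mask
#'
#' Per slice, the cortical shell is the set of bone components
#' (8-connected) in contact with the exterior background (flooded
#' 4-connected from the slice border). Interior bone (trabeculae
#' disconnected from the shell) is excluded.
#'
#' @param mask a \linkS4class{BinaryVolume} of segmented bone.
#' @return A \linkS4class{BinaryVolume} holding the shell.
#' @export
cortexMask <- function(mask) {
  codes <- .regionCodes(mask)
  BinaryVolume(codes == 1L, voxelSize(mask), name = volName(mask))
}

#' Trabecular (endosteal) compartment of a cortical shell
#'
#' Returns the interior region enclosed by the cortical shell: the
#' per-slice morphological filling of the shell minus the shell itself.
#' This programmatic construction replaces operator-drawn contours that
#' include trabecular bone and exclude cortical bone.
#'
#' A slice on which the shell is present but encloses nothing is checked
#' for small gaps by closing the shell with a one-voxel dilation; if the
#' closed shell does enclose an interior the shell is reported as not
#' closed on that slice. A genuinely solid cross-section (no marrow)
#' yields an empty interior without error.
#'
#' @param cortex a \linkS4class{BinaryVolume} (or \linkS4class{RoiMask})
#'   holding the cortical shell.
#' @param slices optional integer range of slices to process (default all).
#' @param label label for the resulting ROI.
#' @return An \linkS4class{RoiMask} of the enclosed compartment.
#' @export
trabecularMask <- function(cortex, slices = NULL,
                           label = "tibial_metaphysis_trab") {
  arr <- volData(cortex)
  if (is.null(slices)) slices <- seq_len(dim(arr)[1])
  codes <- .regionCodes(cortex)
  interior <- array(FALSE, dim(arr))
  for (k in slices) {
    shell <- arr[k, , ]
    if (!any(shell))
      stop("no cortical shell on slice ", k)
    ik <- codes[k, , ] >= 2L   # enclosed background or interior bone
    if (!any(ik)) {
      # distinguish a solid cross-section from a broken ring
      closed <- .dilate2d(shell)
      cc <- .sliceRegionCodesCpp(as.vector(array(closed, c(1, dim(closed)))),
                                 c(1L, dim(closed)))
      if (any(cc >= 2L))
        stop("cortical shell not closed on slice ", k)
    }
    interior[k, , ] <- ik
  }
  # may be empty (e.g. a solid cross-section with no marrow space)
  RoiMask(interior, voxelSize(cortex), label = label,
          name = volName(cortex))
}
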