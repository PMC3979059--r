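#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @export
setGeneric("volData", function(x) standardGeneric("volData"))

#' @export
setGeneric("sliceAxis", function(x) standardGeneric("sliceAxis"))

#' @export
setGeneric("volName", function(x) standardGeneric("volName"))

#' @export
setGeneric("roiLabel", function(x) standardGeneric("roiLabel"))

#' @export
setGeneric("gaussianFilter",
           function(vol, params, ...) standardGeneric("gaussianFilter"))

#' @export
setGeneric("segmentBone",
           function(vol, params, ...) standardGeneric("segmentBone"))
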