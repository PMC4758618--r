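#' @rdname VoxelGrid-class
#' @param object,x a \linkS4class{VoxelGrid}
#' @export
setGeneric("intensityValues", function(x) standardGeneric("intensityValues"))

#' @rdname VoxelGrid-class
#' @export
setGeneric("voxelDims", function(x) standardGeneric("voxelDims"))

#' @rdname VoxelGrid-class
#' @export
setGeneric("channelName", function(x) standardGeneric("channelName"))

#' @export
#' @rdname renderFocus
setGeneric("renderFocus",
  function(grid, center, photons, sigmaXY, sigmaZ)
    standardGeneric("renderFocus"))

#' @export
#' @rdname applyNoise
setGeneric("applyNoise",
  function(grid, optics, seed = NULL) standardGeneric("applyNoise"))

#' @export
#' @rdname findFoci
setGeneric("findFoci",
  function(grid, params = detectionParams()) standardGeneric("findFoci"))

#' @export
#' @rdname measureFocus
setGeneric("measureFocus",
  function(grid, roi) standardGeneric("measureFocus"))

#' @export
#' @rdname roiVolume
setGeneric("roiVolume", function(roi) standardGeneric("roiVolume"))

#' @export
#' @rdname extractPatch
setGeneric("extractPatch",
  function(grid, center, halfWidth = 2L) standardGeneric("extractPatch"))
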