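#' @rdname CloneSet-accessors
#' @export
setGeneric("nuclei", function(x) standardGeneric("nuclei"))

#' @rdname CloneSet-accessors
#' @export
setGeneric("frameOf", function(x) standardGeneric("frameOf"))

#' @rdname CloneSet-accessors
#' @export
setGeneric("cloneIds", function(x) standardGeneric("cloneIds"))

#' @rdname CloneSet-accessors
#' @export
setGeneric("cloneSizes", function(x) standardGeneric("cloneSizes"))

#' @rdname CloneSet-accessors
#' @export
setGeneric("clonePoints", function(x, cloneId) standardGeneric("clonePoints"))

#' @rdname identifyDoublets
#' @export
setGeneric("identifyDoublets", function(x, ...)
  standardGeneric("identifyDoublets"))

#' @rdname DoubletSet-accessors
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))

#' @rdname DoubletSet-accessors
#' @export
setGeneric("dStar", function(x) standardGeneric("dStar"))

#' @rdname ElevationProfile-accessors
#' @export
setGeneric("completeFraction", function(x) standardGeneric("completeFraction"))

#' @rdname ElevationProfile-accessors
#' @export
setGeneric("nDoublets", function(x) standardGeneric("nDoublets"))

#' @rdname ElevationProfile-accessors
#' @export
setGeneric("binCounts", function(x) standardGeneric("binCounts"))

#' @rdname MulticloneSet-accessors
#' @export
setGeneric("groups", function(x) standardGeneric("groups"))

#' @rdname MulticloneSet-accessors
#' @export
setGeneric("mergedClones", function(x) standardGeneric("mergedClones"))

#' @rdname COJSurface-accessors
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))

#' @rdname COJSurface-accessors
#' @export
setGeneric("pitch", function(x) standardGeneric("pitch"))
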