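#' @rdname BoldImage-class
#' @param object,x a `BoldImage`
#' @export
setGeneric("boldData", function(x) standardGeneric("boldData"))

#' @rdname BoldImage-class
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname BoldImage-class
#' @export
setGeneric("repetitionTime", function(x) standardGeneric("repetitionTime"))

#' @rdname BoldImage-class
#' @export
setGeneric("nVolumes", function(x) standardGeneric("nVolumes"))

#' @rdname StatMap-class
#' @param x a `StatMap`
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))

#' @rdname StatMap-class
#' @export
setGeneric("mapKind", function(x) standardGeneric("mapKind"))

#' @rdname StatMap-class
#' @export
setGeneric("mapMask", function(x) standardGeneric("mapMask"))

#' @rdname SeedROI-class
#' @param x a `SeedROI`
#' @export
setGeneric("roiCenter", function(x) standardGeneric("roiCenter"))

#' @rdname SeedROI-class
#' @export
setGeneric("roiMembers", function(x) standardGeneric("roiMembers"))

#' @rdname RoiMask-class
#' @param x a `RoiMask`
#' @export
setGeneric("roiLabels", function(x) standardGeneric("roiLabels"))

#' @rdname RoiMask-class
#' @export
setGeneric("roiTable", function(x) standardGeneric("roiTable"))
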