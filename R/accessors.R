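#' Construct a BoldImage
#'
#' @param data 4D numeric array (x, y, z, t).
#' @param voxelSize voxel edge lengths in mm (length 3).
#' @param TR repetition time in seconds.
#' @return A [BoldImage-class] object.
#' @examples
#' b <- boldImage(array(rnorm(4^3 * 2) , c(4, 4, 4, 2)))
#' nVolumes(b)
#' @export
boldImage <- function(data, voxelSize = c(0.75, 0.75, 1.5), TR = 2.8) {
    if (length(dim(data)) == 3L)
        stop("a 3D volume cannot be a BoldImage; need a 4D (x, y, z, t) array")
    new("BoldImage", data = data, voxelSize = as.numeric(voxelSize),
        TR = as.numeric(TR))
}

#' @rdname BoldImage-class
#' @export
setMethod("boldData", "BoldImage", function(x) x@data)

#' @rdname BoldImage-class
#' @export
setMethod("voxelSize", "BoldImage", function(x) x@voxelSize)

#' @rdname BoldImage-class
#' @export
setMethod("repetitionTime", "BoldImage", function(x) x@TR)

#' @rdname BoldImage-class
#' @export
setMethod("nVolumes", "BoldImage", function(x) dim(x@data)[4])

setMethod("show", "BoldImage", function(object) {
    d <- dim(object@data)
    cat(sprintf("BoldImage: %d x %d x %d voxels, %d volumes\n",
                d[1], d[2], d[3], d[4]))
    cat(sprintf("  voxel size %.3g x %.3g x %.3g mm, TR %.3g s\n",
                object@voxelSize[1], object@voxelSize[2],
                object@voxelSize[3], object@TR))
})

#' Construct a PhysioTrace
#'
#' @param cardiac,respiratory phase vectors in radians, wrapped to
#'   `[0, 2*pi)`.
#' @return A [PhysioTrace-class] object.
#' @export
physioTrace <- function(cardiac, respiratory) {
    new("PhysioTrace", cardiac = cardiac %% (2 * pi),
        respiratory = respiratory %% (2 * pi))
}

setMethod("show", "PhysioTrace", function(object) {
    cat(sprintf("PhysioTrace: %d time points (cardiac + respiratory phase)\n",
                length(object@cardiac)))
})

#' @rdname SeedROI-class
#' @export
setMethod("roiCenter", "SeedROI", function(x) x@center)

#' @rdname SeedROI-class
#' @export
setMethod("roiMembers", "SeedROI", function(x) x@members)

setMethod("show", "SeedROI", function(object) {
    cat(sprintf("SeedROI (%s): center (%d, %d, %d), 9-voxel in-plane ROI\n",
                object@hemisphere, object@center[1], object@center[2],
                object@center[3]))
})

#' Construct a StatMap
#'
#' @param values 3D numeric array (will be masked to `NA` outside `mask`).
#' @param mask logical 3D array.
#' @param kind `"r"`, `"t"` or `"z"`.
#' @param df degrees of freedom (t maps).
#' @return A [StatMap-class] object.
#' @export
statMap <- function(values, mask, kind, df = NA_real_) {
    values[!mask] <- NA_real_
    new("StatMap", values = values, mask = mask, kind = kind,
        df = as.numeric(df))
}

#' @rdname StatMap-class
#' @export
setMethod("mapValues", "StatMap", function(x) x@values)

#' @rdname StatMap-class
#' @export
setMethod("mapKind", "StatMap", function(x) x@kind)

#' @rdname StatMap-class
#' @export
setMethod("mapMask", "StatMap", function(x) x@mask)

setMethod("show", "StatMap", function(object) {
    v <- object@values[object@mask]
    cat(sprintf("StatMap (kind = %s%s): %d in-mask voxels, range [%.3g, %.3g]\n",
                object@kind,
                if (is.finite(object@df)) sprintf(", df = %g", object@df) else "",
                sum(object@mask), min(v, na.rm = TRUE), max(v, na.rm = TRUE)))
})

#' @rdname RoiMask-class
#' @export
setMethod("roiLabels", "RoiMask", function(x) x@labels)

#' @rdname RoiMask-class
#' @export
setMethod("roiTable", "RoiMask", function(x) x@table)

setMethod("show", "RoiMask", function(object) {
    cat(sprintf("RoiMask: %d ROIs, %d labeled voxels\n",
                nrow(object@table), sum(object@labels > 0)))
})
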