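# Readers/writers for the standard formats: NIfTI-1 images, TSV tables,
# YAML configuration. NIfTI handling is delegated to RNifti.

#' Read / write a 4D BOLD NIfTI
#'
#' `readBold()` loads a NIfTI-1 file into a [BoldImage-class], taking voxel
#' size and TR from the header pixdims; `writeBold()` is its inverse. A
#' round trip preserves the data and voxel dimensions to float32 header
#' precision.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `readBold()`: a [BoldImage-class].
#' @export
readBold <- function(path) {
    img <- RNifti::readNifti(path)
    if (length(dim(img)) != 4L)
        stop(sprintf("'%s' is not a 4D image (dims: %s); a 3D volume cannot be read as BOLD",
                     path, paste(dim(img), collapse = "x")))
    pd <- RNifti::pixdim(img)
    boldImage(array(as.numeric(img), dim(img)), voxelSize = pd[1:3],
              TR = if (length(pd) >= 4 && pd[4] > 0) pd[4] else 1)
}

#' @rdname readBold
#' @param bold a [BoldImage-class].
#' @export
writeBold <- function(bold, path) {
    img <- RNifti::asNifti(bold@data)
    RNifti::pixdim(img) <- c(bold@voxelSize, bold@TR)
    RNifti::writeNifti(img, path)
    invisible(path)
}

#' Read / write a 3D mask or label NIfTI
#'
#' Masks are stored as integer volumes; `readMask()` returns a logical
#' array for binary images and an integer array when more than two levels
#' are present.
#'
#' @param path file path.
#' @return Logical or integer 3D array with attribute `"voxelSize"`.
#' @export
readMask <- function(path) {
    img <- RNifti::readNifti(path)
    if (length(dim(img)) != 3L)
        stop(sprintf("'%s' is not a 3D image", path))
    v <- array(as.numeric(img), dim(img))
    if (any(v != round(v)))
        stop(sprintf("'%s' is not integer/boolean-valued", path))
    out <- if (all(v %in% c(0, 1))) array(v == 1, dim(v))
           else array(as.integer(v), dim(v))
    attr(out, "voxelSize") <- RNifti::pixdim(img)[1:3]
    out
}

#' @rdname readMask
#' @param mask logical or integer 3D array.
#' @param voxelSize voxel edge lengths (mm).
#' @export
writeMask <- function(mask, path, voxelSize = c(0.75, 0.75, 1.5)) {
    img <- RNifti::asNifti(array(as.integer(mask), dim(mask)))
    RNifti::pixdim(img) <- voxelSize
    RNifti::writeNifti(img, path)
    invisible(path)
}

#' Read / write tab-separated tables
#'
#' Plain TSV with a header row; used for motion summaries, physiological
#' traces and volume tables.
#'
#' @param path file path.
#' @return `readTsv()`: a data.frame.
#' @export
readTsv <- function(path) {
    utils::read.delim(path, sep = "\t", check.names = FALSE)
}

#' @rdname readTsv
#' @param tab a data.frame.
#' @export
writeTsv <- function(tab, path) {
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Construct a pipeline configuration
#'
#' All stage parameters with their standard defaults: drop 4 initial
#' volumes, order-2 physiological Fourier basis, 2 mm FWHM smoothing,
#' 0.08 Hz low-pass, linear detrend, single-voxel threshold p < 0.0005
#' with cluster extent 500, 2.5-SD motion exclusion, FDR level 0.05,
#' row-maximum seed aggregation, 26-connectivity clusters.
#'
#' @param kDrop,physioOrder,fwhmMm,cutoffHz,detrendOrder,pThresh,minCluster,kSd,q,aggregate,connectivity,seed
#'   see [PipelineConfig-class].
#' @return A validated [PipelineConfig-class].
#' @export
pipelineConfig <- function(kDrop = 4L, physioOrder = 2L, fwhmMm = 2.0,
                           cutoffHz = 0.08, detrendOrder = 1L,
                           pThresh = 5e-4, minCluster = 500L, kSd = 2.5,
                           q = 0.05, aggregate = "max", connectivity = 26L,
                           seed = 1L) {
    new("PipelineConfig", kDrop = as.integer(kDrop),
        physioOrder = as.integer(physioOrder), fwhmMm = as.numeric(fwhmMm),
        cutoffHz = as.numeric(cutoffHz),
        detrendOrder = as.integer(detrendOrder), pThresh = as.numeric(pThresh),
        minCluster = as.integer(minCluster), kSd = as.numeric(kSd),
        q = as.numeric(q), aggregate = aggregate,
        connectivity = as.integer(connectivity), seed = as.integer(seed))
}

configSlots <- c("kDrop", "physioOrder", "fwhmMm", "cutoffHz", "detrendOrder",
                 "pThresh", "minCluster", "kSd", "q", "aggregate",
                 "connectivity", "seed")

#' Serialize / restore a pipeline configuration
#'
#' YAML round trip is lossless: `readPipelineConfig(writePipelineConfig(x))`
#' is identical to `x`.
#'
#' @param config a [PipelineConfig-class].
#' @param path YAML file path.
#' @export
writePipelineConfig <- function(config, path) {
    validObject(config)
    vals <- lapply(configSlots, function(s) slot(config, s))
    names(vals) <- configSlots
    yaml::write_yaml(vals, path)
    invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
    vals <- yaml::read_yaml(path)
    do.call(pipelineConfig, vals[configSlots])
}

setMethod("show", "PipelineConfig", function(object) {
    cat("PipelineConfig:\n")
    for (s in configSlots)
        cat(sprintf("  %-13s %s\n", s, format(slot(object, s))))
})
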