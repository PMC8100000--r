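# Group-level maps: averaging, single-voxel + cluster-extent thresholding,
# union ROI definition, and per-subject ROI mean-z extraction.

stackMaps <- function(zMaps) {
    d <- dim(zMaps[[1]]@values)
    for (m in zMaps)
        checkSameGrid(m@values, zMaps[[1]]@values, "z maps")
    vapply(zMaps, function(m) m@values, array(0, d))
}

#' Voxelwise group mean map
#'
#' Arithmetic mean over subjects' (co-registered) z maps.
#'
#' @param zMaps list of >= 2 [StatMap-class] objects on one grid.
#' @return A [StatMap-class] of the same kind.
#' @export
groupMeanMap <- function(zMaps) {
    if (length(zMaps) < 2L) stop("need at least 2 maps")
    arr <- stackMaps(zMaps)
    vals <- apply(arr, 1:3, mean)
    statMap(vals, zMaps[[1]]@mask, zMaps[[1]]@kind)
}

#' Threshold a group of maps voxelwise
#'
#' Per voxel, a two-sided one-sample t-test of the subjects' z values
#' against zero (`df = n - 1`); the returned mask holds voxels with
#' `p < pThresh`. Voxels with zero across-subject variance are excluded
#' with a warning.
#'
#' @param zMaps list of >= 3 [StatMap-class] objects on one grid.
#' @param pThresh single-voxel threshold (default 5e-4).
#' @return Logical 3D array.
#' @export
thresholdMap <- function(zMaps, pThresh = 5e-4) {
    n <- length(zMaps)
    if (n < 3L) stop("need at least 3 subjects")
    arr <- stackMaps(zMaps)
    d <- dim(arr)[1:3]
    m <- matrix(arr, prod(d), n)
    mask <- zMaps[[1]]@mask
    inIdx <- which(mask)
    sub <- m[inIdx, , drop = FALSE]
    mu <- rowMeans(sub)
    s <- rowSds(sub)
    zerovar <- s == 0
    if (any(zerovar))
        warning(sprintf("%d voxel(s) with zero across-subject variance excluded",
                        sum(zerovar)))
    tstat <- mu / (s / sqrt(n))
    p <- 2 * stats::pt(-abs(tstat), df = n - 1)
    sig <- !zerovar & is.finite(p) & p < pThresh
    out <- array(FALSE, d)
    out[inIdx[sig]] <- TRUE
    out
}

#' Cluster-extent filter
#'
#' Labels connected components of a binary mask under the chosen 3D
#' connectivity and removes components smaller than `minSize` voxels.
#'
#' @param mask logical 3D array.
#' @param minSize minimum cluster extent in voxels (default 500).
#' @param connectivity 6, 18 or 26 (default 26).
#' @return Logical 3D array with only the surviving clusters.
#' @export
clusterFilter <- function(mask, minSize = 500L, connectivity = 26L) {
    if (minSize <= 1L) return(mask)
    labs <- labelComponents(mask, connectivity)
    if (max(labs) == 0L) return(mask)
    sizes <- tabulate(labs[labs > 0])
    keep <- which(sizes >= minSize)
    array(labs %in% keep, dim(mask))
}

#' Union of thresholded maps into labeled ROIs
#'
#' Adds the four thresholded group maps (left/right seed in each group) into
#' a single mask of regions significantly connected to either hippocampus in
#' either group, then labels its connected components (26-connectivity by
#' default) as ROIs.
#'
#' @param masks list of logical 3D arrays on one grid (any number >= 1;
#'   the group analysis uses four).
#' @param connectivity component connectivity (default 26).
#' @return A [RoiMask-class]; errors if the union is empty.
#' @export
unionConjunction <- function(masks, connectivity = 26L) {
    u <- masks[[1]]
    for (m in masks[-1]) {
        checkSameGrid(m, u, "masks")
        u <- u | m
    }
    if (!any(u)) stop("union of thresholded maps is empty")
    labs <- labelComponents(u, connectivity)
    k <- max(labs)
    tab <- data.frame(label = seq_len(k),
                      name = sprintf("ROI %d", seq_len(k)),
                      nVoxels = tabulate(labs[labs > 0], nbins = k))
    new("RoiMask", labels = labs, table = tab)
}

#' Per-ROI mean z
#'
#' Unweighted mean of a subject's z map over each ROI label.
#'
#' @param zMap a [StatMap-class].
#' @param rois a [RoiMask-class] on the same grid.
#' @return data.frame: `label`, `name`, `nVoxels`, `meanZ`. ROIs with no
#'   finite map values yield `NA` with a warning.
#' @export
roiMeanZ <- function(zMap, rois) {
    checkSameGrid(zMap@values, rois@labels, "map and ROI labels")
    tab <- rois@table
    mz <- vapply(tab$label, function(l) {
        v <- zMap@values[rois@labels == l]
        v <- v[is.finite(v)]
        if (length(v) == 0L) NA_real_ else mean(v)
    }, numeric(1))
    if (anyNA(mz))
        warning("ROI(s) with no finite map values flagged as NA")
    cbind(tab, meanZ = mz)
}
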