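# Seed selection (hippocampus-to-PCC cross-correlation search) and
# connectivity map creation with whole-brain z normalization.

#' Conjunction (AND) of two masks
#'
#' Voxelwise AND of a network mask and a grey-matter mask, used to restrict
#' the PCC search region to grey-matter voxels of the network parcel.
#'
#' @param networkMask,gmMask logical 3D arrays on the same grid.
#' @return Logical 3D array. Warns if the result is empty.
#' @export
conjunctionMask <- function(networkMask, gmMask) {
    checkSameGrid(networkMask, gmMask, "masks")
    out <- networkMask & gmMask
    if (!any(out))
        warning("conjunction mask is empty")
    out
}

#' Cross-correlate two regions voxel by voxel
#'
#' Pearson correlation of every voxel time series in `regionA` against every
#' voxel time series in `regionB`. Zero-variance voxels yield `NA` entries
#' (flagged with a warning) and are ignored by downstream maxima.
#'
#' @param bold a [BoldImage-class].
#' @param regionA,regionB nonempty logical 3D arrays on the image grid.
#' @return list: `corr` (`|A| x |B|` matrix), `voxelsA`, `voxelsB`
#'   (index matrices, rows aligned with `corr` dimensions).
#' @export
crossCorrelateRegions <- function(bold, regionA, regionB) {
    d <- dim(bold@data)[1:3]
    checkSameGrid(regionA, array(0, d), "region A and image")
    checkSameGrid(regionB, array(0, d), "region B and image")
    if (!any(regionA) || !any(regionB))
        stop("both regions must be nonempty")
    m <- boldToMatrix(bold)                     # nt x nvox
    ia <- which(regionA)
    ib <- which(regionB)
    A <- m[, ia, drop = FALSE]
    B <- m[, ib, drop = FALSE]
    zvA <- apply(A, 2, sd) == 0
    zvB <- apply(B, 2, sd) == 0
    if (any(zvA) || any(zvB))
        warning(sprintf("%d zero-variance voxels flagged", sum(zvA) + sum(zvB)))
    cc <- suppressWarnings(stats::cor(A, B))
    cc[zvA, ] <- NA_real_
    cc[, zvB] <- NA_real_
    list(corr = cc,
         voxelsA = which(regionA, arr.ind = TRUE),
         voxelsB = which(regionB, arr.ind = TRUE))
}

#' Select the seed voxel from a cross-correlation matrix
#'
#' Identifies the candidate (row) voxel with the highest correlation to the
#' target region: each row is aggregated over target voxels by its maximum
#' (default) or mean, and the argmax row is returned. Ties are broken by the
#' lowest row index (rows are in x-fastest linear voxel order), making the
#' choice deterministic.
#'
#' @param corr correlation matrix (rows = candidate voxels) or the list
#'   returned by [crossCorrelateRegions()].
#' @param aggregate `"max"` (default) or `"mean"` row aggregation.
#' @return Row index of the selected voxel; if `corr` came from
#'   [crossCorrelateRegions()], the attribute `"voxel"` carries its
#'   (x, y, z) index.
#' @export
selectSeedVoxel <- function(corr, aggregate = c("max", "mean")) {
    aggregate <- match.arg(aggregate)
    voxels <- NULL
    if (is.list(corr) && !is.null(corr$corr)) {
        voxels <- corr$voxelsA
        corr <- corr$corr
    }
    if (!is.matrix(corr) || length(corr) == 0)
        stop("corr must be a nonempty matrix")
    agg <- if (aggregate == "max") {
        suppressWarnings(apply(corr, 1, max, na.rm = TRUE))
    } else {
        rowMeans(corr, na.rm = TRUE)
    }
    agg[!is.finite(agg)] <- NA_real_
    if (all(is.na(agg)))
        stop("all correlation entries are undefined")
    sel <- which.max(agg)  # first maximum = lowest index tie-break
    if (!is.null(voxels))
        attr(sel, "voxel") <- as.integer(voxels[sel, ])
    sel
}

#' Build the 9-voxel in-plane seed ROI
#'
#' Takes the selected hippocampal voxel as the center of a 3 x 3 in-plane
#' (axial, fixed z) neighborhood. Members falling outside the hippocampal
#' mask are kept but reported with a warning.
#'
#' @param center (x, y, z) voxel index inside `hipMask`.
#' @param hipMask logical 3D array.
#' @param hemisphere `"L"` or `"R"`.
#' @return A [SeedROI-class].
#' @export
makeInplaneROI <- function(center, hipMask, hemisphere = "L") {
    center <- as.integer(center)
    d <- dim(hipMask)
    if (!hipMask[center[1], center[2], center[3]])
        stop("center voxel is not inside the hippocampal mask")
    if (center[1] < 2 || center[1] > d[1] - 1 ||
        center[2] < 2 || center[2] > d[2] - 1)
        stop("3x3 in-plane neighborhood crosses the grid boundary")
    members <- as.matrix(expand.grid(x = center[1] + (-1:1),
                                     y = center[2] + (-1:1),
                                     z = center[3]))
    members <- matrix(as.integer(members), ncol = 3,
                      dimnames = list(NULL, c("x", "y", "z")))
    outside <- !hipMask[members]
    if (any(outside))
        warning(sprintf("%d ROI member voxel(s) outside the hippocampal mask: %s",
                        sum(outside),
                        paste(apply(members[outside, , drop = FALSE], 1,
                                    paste, collapse = ","), collapse = "; ")))
    new("SeedROI", center = center, members = members,
        hemisphere = hemisphere)
}

#' Seed mean time series
#'
#' Unweighted mean over the ROI's 9 voxels, then linearly detrended.
#'
#' @param bold a [BoldImage-class].
#' @param roi a [SeedROI-class].
#' @return Numeric vector of length `nt`.
#' @export
seedTimeseries <- function(bold, roi) {
    d <- dim(bold@data)
    nt <- d[4]
    m <- roi@members
    lin <- m[, 1] + (m[, 2] - 1L) * d[1] + (m[, 3] - 1L) * d[1] * d[2]
    mat <- boldToMatrix(bold)[, lin, drop = FALSE]
    temporalDetrend(rowMeans(mat))
}

#' Voxelwise seed connectivity map
#'
#' Pearson correlation between the (detrended) seed series and the linearly
#' detrended time series of every voxel inside the brain mask.
#'
#' @param bold a [BoldImage-class].
#' @param seedSeries numeric vector (length `nt`), typically from
#'   [seedTimeseries()].
#' @param brain logical 3D brain mask.
#' @return A [StatMap-class] of kind `"r"`; zero-variance voxels are `NA`.
#' @export
voxelwiseConnectivity <- function(bold, seedSeries, brain) {
    d <- dim(bold@data)
    checkSameGrid(brain, array(0, d[1:3]), "brain mask and image")
    if (d[4] < 4L) stop("need at least 4 time points")
    if (sd(seedSeries) == 0) stop("seed series has zero variance")
    idx <- which(brain)
    m <- boldToMatrix(bold)[, idx, drop = FALSE]
    m <- detrendMatrix(m, 1L)
    seedSeries <- seedSeries - mean(seedSeries)
    denom <- sqrt(colSums(m^2)) * sqrt(sum(seedSeries^2))
    r <- as.numeric(crossprod(m, seedSeries)) / denom
    r[denom == 0] <- NA_real_
    vals <- array(NA_real_, d[1:3])
    vals[idx] <- r
    statMap(vals, brain, "r")
}

#' Convert a correlation map to Student t
#'
#' `t = r * sqrt(df) / sqrt(1 - r^2)` with `df = nTimepoints - 2`, recorded
#' in the map. Voxels with `|r| = 1` map to signed infinity and are flagged
#' with a warning (they are excluded later by [normalizeMap()]).
#'
#' @param map a [StatMap-class] of kind `"r"`.
#' @param nTimepoints number of time points the correlations were computed
#'   from (>= 4).
#' @return A [StatMap-class] of kind `"t"`.
#' @export
rToT <- function(map, nTimepoints) {
    if (map@kind != "r") stop("input map must be of kind \"r\"")
    if (nTimepoints < 4L) stop("need at least 4 time points")
    df <- nTimepoints - 2
    r <- map@values
    sat <- map@mask & is.finite(r) & abs(r) >= 1
    if (any(sat))
        warning(sprintf("%d voxel(s) with |r| = 1 mapped to infinite t",
                        sum(sat)))
    tval <- r * sqrt(df) / sqrt(pmax(1 - r^2, 0))
    statMap(tval, map@mask, "t", df = df)
}

#' Normalize a map over the brain mask
#'
#' Centers and scales the whole-brain distribution to zero mean and unit
#' variance (sample sd), correcting for individual variations in global
#' signal. Non-finite in-mask values are excluded from the statistics and
#' remain non-finite in the output.
#'
#' @param map a [StatMap-class] (typically kind `"t"`).
#' @param brain optional logical mask overriding the map's own mask.
#' @return A [StatMap-class] of kind `"z"` with in-mask mean 0 and sd 1.
#' @export
normalizeMap <- function(map, brain = NULL) {
    mask <- if (is.null(brain)) map@mask else brain
    v <- map@values[mask]
    v <- v[is.finite(v)]
    if (length(v) < 2L)
        stop("need at least 2 finite in-mask values")
    s <- sd(v)
    if (s == 0) stop("cannot normalize a zero-variance map")
    z <- (map@values - mean(v)) / s
    statMap(z, mask, "z")
}
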