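#' @import methods
NULL

#' 4D BOLD image
#'
#' A 4D functional MRI time series on a regular voxel grid, together with the
#' voxel size and repetition time (TR). This is the container every
#' preprocessing and connectivity operation consumes and returns.
#'
#' @slot data numeric 4D array, `nx x ny x nz x nt`, in arbitrary signal units.
#' @slot voxelSize numeric length-3, voxel edge length in mm per axis.
#' @slot TR numeric scalar, repetition time in seconds.
#'
#' @seealso [boldImage()], [dropInitialVolumes()], [voxelwiseConnectivity()]
#' @export
setClass("BoldImage",
    representation(data = "array", voxelSize = "numeric", TR = "numeric"))

setValidity("BoldImage", function(object) {
    d <- object@data
    if (length(dim(d)) != 4L)
        return("data must be a 4D array (x, y, z, t)")
    if (dim(d)[4] < 2L)
        return("need at least 2 time points")
    if (!all(is.finite(d)))
        return("data must be finite")
    if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
        return("voxelSize must be 3 positive values (mm)")
    if (length(object@TR) != 1L || !is.finite(object@TR) || object@TR <= 0)
        return("TR must be a positive scalar (s)")
    TRUE
})

#' Physiological phase traces
#'
#' Cardiac and respiratory phase per acquired volume, in radians on
#' `[0, 2*pi)`, as measured by a plethysmograph and respiratory bellows (or
#' simulated). Used to build RETROICOR-style Fourier confound regressors.
#'
#' @slot cardiac numeric vector of cardiac phases (radians), length nt.
#' @slot respiratory numeric vector of respiratory phases (radians), length nt.
#'
#' @seealso [buildPhysioRegressors()]
#' @export
setClass("PhysioTrace",
    representation(cardiac = "numeric", respiratory = "numeric"))

setValidity("PhysioTrace", function(object) {
    if (length(object@cardiac) != length(object@respiratory))
        return("cardiac and respiratory traces must have equal length")
    ph <- c(object@cardiac, object@respiratory)
    if (!all(is.finite(ph)))
        return("phases must be finite")
    if (any(ph < 0) || any(ph >= 2 * pi))
        return("phases must lie in [0, 2*pi)")
    TRUE
})

#' Seed region of interest
#'
#' The selected hippocampal seed: a center voxel plus its 9-voxel in-plane
#' (axial, fixed z) 3x3 neighborhood.
#'
#' @slot center integer length-3 voxel index (x, y, z).
#' @slot members 9x3 integer matrix of member voxel indices.
#' @slot hemisphere character, `"L"` or `"R"`.
#'
#' @seealso [makeInplaneROI()], [seedTimeseries()]
#' @export
setClass("SeedROI",
    representation(center = "integer", members = "matrix",
                   hemisphere = "character"))

setValidity("SeedROI", function(object) {
    m <- object@members
    if (!is.matrix(m) || nrow(m) != 9L || ncol(m) != 3L)
        return("members must be a 9 x 3 index matrix")
    if (length(object@center) != 3L)
        return("center must be an (x, y, z) index")
    if (length(unique(m[, 3])) != 1L || m[1, 3] != object@center[3])
        return("members must share the center's z slice (in-plane)")
    ctr <- matrix(object@center, 9, 3, byrow = TRUE)
    if (any(abs(m[, 1:2] - ctr[, 1:2]) > 1L))
        return("members must form the 3x3 in-plane neighborhood of center")
    if (!any(m[, 1] == object@center[1] & m[, 2] == object@center[2]))
        return("center must be a member")
    if (anyDuplicated(m))
        return("members must be distinct voxels")
    if (!object@hemisphere %in% c("L", "R"))
        return("hemisphere must be \"L\" or \"R\"")
    TRUE
})

#' Voxelwise statistical map
#'
#' A voxelwise map (Pearson r, Student t, or normalized z) defined over a
#' brain mask. Values outside the mask are `NA`; non-finite in-mask values
#' mark degenerate voxels (e.g. |r| = 1 mapped to infinite t).
#'
#' @slot values numeric 3D array; `NA` outside the mask.
#' @slot mask logical 3D array, same dimensions.
#' @slot kind character, one of `"r"`, `"t"`, `"z"`.
#' @slot df numeric, degrees of freedom (for `kind = "t"`; `NA` otherwise).
#'
#' @seealso [voxelwiseConnectivity()], [rToT()], [normalizeMap()]
#' @export
setClass("StatMap",
    representation(values = "array", mask = "array", kind = "character",
                   df = "numeric"))

setValidity("StatMap", function(object) {
    if (length(dim(object@values)) != 3L)
        return("values must be a 3D array")
    if (!identical(dim(object@values), dim(object@mask)))
        return("values and mask dimensions differ")
    if (!is.logical(object@mask))
        return("mask must be logical")
    if (!object@kind %in% c("r", "t", "z"))
        return("kind must be one of \"r\", \"t\", \"z\"")
    v <- object@values[object@mask]
    if (object@kind == "r" && any(abs(v[is.finite(v)]) > 1 + 1e-12))
        return("|r| must not exceed 1 inside the mask")
    if (any(!is.na(object@values[!object@mask])))
        return("values outside the mask must be NA")
    TRUE
})

#' Labeled ROI mask
#'
#' An integer label image defining regions of interest (connected components
#' of a thresholded group map union), plus a label table naming each region.
#'
#' @slot labels integer 3D array; 0 = background, 1..K = ROI labels.
#' @slot table data.frame with columns `label`, `name`, `nVoxels`.
#'
#' @seealso [unionConjunction()], [roiMeanZ()]
#' @export
setClass("RoiMask",
    representation(labels = "array", table = "data.frame"))

setValidity("RoiMask", function(object) {
    if (length(dim(object@labels)) != 3L)
        return("labels must be a 3D array")
    labs <- sort(unique(as.integer(object@labels[object@labels > 0])))
    if (length(labs) == 0L)
        return("ROI mask must contain at least one labeled voxel")
    if (!identical(labs, seq_along(labs)))
        return("labels must be contiguous from 1")
    if (!identical(sort(object@table$label), labs))
        return("label table must list every label exactly once")
    TRUE
})

#' Synthetic phantom specification
#'
#' Geometry, acquisition and signal parameters for the synthetic BOLD phantom:
#' a brain ellipsoid containing left/right hippocampal-head boxes and a
#' posterior-cingulate (PCC) box nested in a default-mode-network (DMN) box.
#' One designated voxel per hippocampal head is coupled to the PCC latent
#' signal at Pearson `rTarget`.
#'
#' Defaults mirror a 7T resting-state acquisition (TR 2.8 s, 132 volumes,
#' 0.75 x 0.75 x 1.5 mm voxels) on a desk-scale 32 x 32 x 24 grid.
#'
#' @slot dims integer length-3 grid size (voxels).
#' @slot voxelSize numeric length-3 (mm).
#' @slot TR numeric, repetition time (s).
#' @slot nVolumes integer, number of time points.
#' @slot rTarget numeric in `[0, 1)`, planted hippocampus-PCC coupling.
#' @slot pccWeight numeric in `(0, 1]`, latent-signal weight inside the PCC
#'   region (regional SNR of the PCC signal).
#' @slot noiseSd numeric > 0, thermal noise sd (signal units).
#' @slot cardiacAmp,respAmp numeric >= 0, confound sinusoid amplitudes.
#' @slot cardiacFreq,respFreq numeric > 0, confound frequencies (Hz).
#' @slot baseline numeric, additive tissue baseline (signal units).
#' @slot seed integer RNG seed.
#'
#' @seealso [phantomSpec()], [makePhantomAnatomy()], [simulateBold()]
#' @export
setClass("PhantomSpec",
    representation(dims = "integer", voxelSize = "numeric", TR = "numeric",
                   nVolumes = "integer", rTarget = "numeric",
                   pccWeight = "numeric", noiseSd = "numeric",
                   cardiacAmp = "numeric", respAmp = "numeric",
                   cardiacFreq = "numeric", respFreq = "numeric",
                   baseline = "numeric", seed = "integer"))

setValidity("PhantomSpec", function(object) {
    if (length(object@dims) != 3L || any(object@dims < 16L))
        return("grid dims must be >= 16 voxels per axis")
    if (object@nVolumes < 8L)
        return("nVolumes must be >= 8")
    if (object@rTarget < 0 || object@rTarget >= 1)
        return("rTarget must lie in [0, 1)")
    if (object@pccWeight <= 0 || object@pccWeight > 1)
        return("pccWeight must lie in (0, 1]")
    if (object@noiseSd <= 0)
        return("noiseSd must be positive")
    if (object@TR <= 0)
        return("TR must be positive")
    if (any(c(object@cardiacAmp, object@respAmp) < 0))
        return("confound amplitudes must be non-negative")
    TRUE
})

#' Synthetic cohort specification
#'
#' Per-group distribution parameters for the volumetric cohort generator:
#' group sizes, per-measure means and sds (ICV plus left/right subfield
#' volumes in mm3), age range and sex ratio. Defaults reproduce the
#' group-averaged subfield volumes of a trisomy-21 (DS) cohort and
#' age-matched controls (HC).
#'
#' @slot nPerGroup named integer, subjects per group (`DS`, `HC`).
#' @slot means,sds data.frame: one row per measure (`measure` column), columns
#'   `DS` and `HC` (mm3).
#' @slot ageRange numeric length-2 (years).
#' @slot maleFraction named numeric in `[0, 1]` per group.
#' @slot volumeCorrelation numeric in `[0, 1)`: shared per-subject scaling
#'   factor inducing positive correlation between subfield volumes (0 =
#'   independent draws).
#' @slot seed integer RNG seed.
#'
#' @seealso [cohortSpec()], [simulateCohortVolumes()]
#' @export
setClass("CohortSpec",
    representation(nPerGroup = "integer", means = "data.frame",
                   sds = "data.frame", ageRange = "numeric",
                   maleFraction = "numeric", volumeCorrelation = "numeric",
                   seed = "integer"))

setValidity("CohortSpec", function(object) {
    if (any(object@nPerGroup < 3L))
        return("need n >= 3 per group")
    if (!identical(object@means$measure, object@sds$measure))
        return("means and sds must list the same measures in the same order")
    if (any(as.matrix(object@sds[, c("DS", "HC")]) <= 0))
        return("all sds must be positive")
    if (any(as.matrix(object@means[, c("DS", "HC")]) < 0))
        return("means must be non-negative")
    if (diff(object@ageRange) < 0)
        return("ageRange must be increasing")
    if (object@volumeCorrelation < 0 || object@volumeCorrelation >= 1)
        return("volumeCorrelation must lie in [0, 1)")
    TRUE
})

#' Pipeline configuration
#'
#' Every tunable parameter of the end-to-end pipeline, serializable to and
#' from YAML without loss.
#'
#' @slot kDrop integer, initial volumes discarded (default 4).
#' @slot physioOrder integer, Fourier order of the confound basis (default 2).
#' @slot fwhmMm numeric, spatial smoothing FWHM in mm (default 2).
#' @slot cutoffHz numeric, temporal low-pass cutoff in Hz (default 0.08).
#' @slot detrendOrder integer, polynomial detrend order (default 1, linear).
#' @slot pThresh numeric, single-voxel threshold (default 5e-4).
#' @slot minCluster integer, cluster-extent threshold in voxels (default 500).
#' @slot kSd numeric, motion-exclusion multiplier (default 2.5).
#' @slot q numeric, FDR level (default 0.05).
#' @slot aggregate character, seed-search row aggregate: `"max"` or `"mean"`.
#' @slot connectivity integer, cluster connectivity: 6, 18 or 26.
#' @slot seed integer RNG seed for the synthetic stages.
#'
#' @seealso [pipelineConfig()], [runPipeline()]
#' @export
setClass("PipelineConfig",
    representation(kDrop = "integer", physioOrder = "integer",
                   fwhmMm = "numeric", cutoffHz = "numeric",
                   detrendOrder = "integer", pThresh = "numeric",
                   minCluster = "integer", kSd = "numeric", q = "numeric",
                   aggregate = "character", connectivity = "integer",
                   seed = "integer"))

setValidity("PipelineConfig", function(object) {
    if (object@kDrop < 0L) return("kDrop must be >= 0")
    if (object@physioOrder < 1L) return("physioOrder must be >= 1")
    if (object@fwhmMm < 0) return("fwhmMm must be >= 0")
    if (object@cutoffHz <= 0) return("cutoffHz must be positive")
    if (object@detrendOrder < 1L) return("detrendOrder must be >= 1")
    if (object@pThresh <= 0 || object@pThresh >= 1)
        return("pThresh must lie in (0, 1)")
    if (object@minCluster < 1L) return("minCluster must be >= 1")
    if (object@kSd <= 0) return("kSd must be positive")
    if (object@q <= 0 || object@q >= 1) return("q must lie in (0, 1)")
    if (!object@aggregate %in% c("max", "mean"))
        return("aggregate must be \"max\" or \"mean\"")
    if (!object@connectivity %in% c(6L, 18L, 26L))
        return("connectivity must be 6, 18 or 26")
    TRUE
})
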