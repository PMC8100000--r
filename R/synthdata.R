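#' Specify a synthetic BOLD phantom
#'
#' Builds a validated [PhantomSpec-class]. The defaults emulate the
#' resting-state acquisition the pipeline targets — 132 volumes at
#' TR = 2.8 s, 0.75 x 0.75 x 1.5 mm voxels — on a 32 x 32 x 24 grid small
#' enough for desk-scale simulation. One voxel per hippocampal head is
#' coupled to a latent posterior-cingulate (PCC) signal at Pearson
#' `rTarget`; cardiac and respiratory confound sinusoids with measured
#' phase are added throughout brain tissue so that confound regression is
#' verifiable against ground truth.
#'
#' @param dims grid size in voxels (length 3, each >= 16).
#' @param voxelSize voxel edge lengths (mm).
#' @param TR repetition time (s).
#' @param nVolumes number of time points (>= 8).
#' @param rTarget planted hippocampus-PCC coupling, in `[0, 1)`.
#' @param pccWeight latent-signal weight of PCC-region voxels, in `(0, 1]`.
#' @param noiseSd thermal noise sd (signal units).
#' @param cardiacAmp,respAmp confound sinusoid amplitudes (signal units).
#' @param cardiacFreq,respFreq confound frequencies (Hz).
#' @param baseline additive tissue baseline (signal units).
#' @param seed integer RNG seed.
#' @return A [PhantomSpec-class] object.
#' @examples
#' spec <- phantomSpec(seed = 7)
#' anat <- makePhantomAnatomy(spec)
#' sum(anat$hipHeadL)
#' @export
phantomSpec <- function(dims = c(32L, 32L, 24L),
                        voxelSize = c(0.75, 0.75, 1.5),
                        TR = 2.8, nVolumes = 132L,
                        rTarget = 0.6, pccWeight = 0.85,
                        noiseSd = 1, cardiacAmp = 0.3, respAmp = 0.3,
                        cardiacFreq = 1.0, respFreq = 0.3,
                        baseline = 100, seed = 1L) {
    new("PhantomSpec", dims = as.integer(dims),
        voxelSize = as.numeric(voxelSize), TR = as.numeric(TR),
        nVolumes = as.integer(nVolumes), rTarget = as.numeric(rTarget),
        pccWeight = as.numeric(pccWeight), noiseSd = as.numeric(noiseSd),
        cardiacAmp = as.numeric(cardiacAmp), respAmp = as.numeric(respAmp),
        cardiacFreq = as.numeric(cardiacFreq), respFreq = as.numeric(respFreq),
        baseline = as.numeric(baseline), seed = as.integer(seed))
}

# fractional index range on an axis of length n
frange <- function(f1, f2, n) max(1L, round(f1 * n)):min(n, round(f2 * n))

boxMask <- function(dims, xr, yr, zr) {
    m <- array(FALSE, dims)
    m[xr, yr, zr] <- TRUE
    m
}

ellipsoidMask <- function(dims, frac = 0.46) {
    ctr <- (dims + 1) / 2
    ax <- frac * dims
    x <- ((seq_len(dims[1]) - ctr[1]) / ax[1])^2
    y <- ((seq_len(dims[2]) - ctr[2]) / ax[2])^2
    z <- ((seq_len(dims[3]) - ctr[3]) / ax[3])^2
    outer(outer(x, y, "+"), z, "+") <= 1
}

#' Generate phantom anatomy
#'
#' Creates the five aligned masks the pipeline needs: a brain ellipsoid,
#' left and right hippocampal-head boxes, a PCC grey-matter box, and a
#' larger default-mode-network (DMN) box containing the PCC. The regions
#' stand in for anatomically identified hippocampal heads and a
#' network-parcellation-derived PCC mask; the pipeline operators only
#' require aligned masks, so boxes and an ellipsoid suffice.
#'
#' @param spec a [PhantomSpec-class].
#' @return A named list of logical 3D arrays: `brain`, `hipHeadL`,
#'   `hipHeadR`, `pccGm`, `dmnNetwork`.
#' @export
makePhantomAnatomy <- function(spec) {
    validObject(spec)
    d <- spec@dims
    brain <- ellipsoidMask(d)
    hipHeadL <- boxMask(d, frange(0.19, 0.31, d[1]), frange(0.44, 0.56, d[2]),
                        frange(0.42, 0.58, d[3]))
    hipHeadR <- boxMask(d, frange(0.69, 0.81, d[1]), frange(0.44, 0.56, d[2]),
                        frange(0.42, 0.58, d[3]))
    pccGm <- boxMask(d, frange(0.44, 0.56, d[1]), frange(0.78, 0.88, d[2]),
                     frange(0.42, 0.58, d[3]))
    dmnNetwork <- boxMask(d, frange(0.38, 0.63, d[1]), frange(0.72, 0.91, d[2]),
                          frange(0.33, 0.63, d[3]))
    regions <- list(hipHeadL = hipHeadL, hipHeadR = hipHeadR, pccGm = pccGm,
                    dmnNetwork = dmnNetwork)
    for (nm in names(regions))
        if (any(regions[[nm]] & !brain))
            stop(sprintf("geometry error: region '%s' extends outside the brain ellipsoid", nm))
    if (any(hipHeadL & hipHeadR) || any(hipHeadL & pccGm) ||
        any(hipHeadR & pccGm))
        stop("geometry error: hippocampal and PCC regions must be disjoint")
    if (any(pccGm & !dmnNetwork))
        stop("geometry error: PCC mask must be contained in the DMN mask")
    c(list(brain = brain), regions)
}

# center voxel of a box mask, as (x, y, z)
maskCenterVoxel <- function(mask) {
    idx <- which(mask, arr.ind = TRUE)
    ctr <- round(colMeans(idx))
    # snap to the member nearest the centroid
    d2 <- rowSums((idx - matrix(ctr, nrow(idx), 3, byrow = TRUE))^2)
    as.integer(idx[which.min(d2), ])
}

#' Simulate a BOLD phantom with planted connectivity
#'
#' Fills the phantom anatomy with a 4D time series. A standard-normal latent
#' PCC signal drives: (i) one designated voxel per hippocampal head, mixed as
#' `rTarget * latent + sqrt(1 - rTarget^2) * noise` so its expected Pearson
#' correlation with the latent is `rTarget`; (ii) every PCC-region voxel,
#' mixed with weight `pccWeight`. All other brain voxels are independent
#' Gaussian noise. Cardiac and respiratory cosine confounds with recorded
#' phase are added to every brain voxel, and a constant tissue baseline is
#' applied. Voxels outside the brain are zero. Output is a pure function of
#' the spec (including its seed).
#'
#' @param anatomy masks from [makePhantomAnatomy()] on the same grid.
#' @param spec a [PhantomSpec-class].
#' @return list with `bold` ([BoldImage-class]), `truth` (list:
#'   `plantedL`, `plantedR` voxel indices, `latent` signal, `regions`),
#'   and `physio` ([PhysioTrace-class]).
#' @export
simulateBold <- function(anatomy, spec) {
    validObject(spec)
    checkSameGrid(anatomy$brain, array(0, spec@dims), "anatomy and spec grid")
    if (spec@nVolumes < 8L)
        stop("need at least 8 volumes")
    d <- spec@dims
    nt <- spec@nVolumes
    withr::local_seed(spec@seed)

    latent <- rnorm(nt)
    latent <- as.numeric(scale(latent))  # exact unit variance, zero mean

    tsec <- (seq_len(nt) - 1) * spec@TR
    phC <- (2 * pi * spec@cardiacFreq * tsec + runif(1, 0, 2 * pi)) %% (2 * pi)
    phR <- (2 * pi * spec@respFreq * tsec + runif(1, 0, 2 * pi)) %% (2 * pi)
    confound <- spec@cardiacAmp * cos(phC) + spec@respAmp * cos(phR)

    brainIdx <- which(anatomy$brain)
    nb <- length(brainIdx)
    mat <- matrix(rnorm(nb * nt), nb, nt)  # rows: brain voxels

    pccRows <- match(which(anatomy$pccGm), brainIdx)
    w <- spec@pccWeight
    mat[pccRows, ] <- w * matrix(latent, length(pccRows), nt, byrow = TRUE) +
        sqrt(1 - w^2) * mat[pccRows, ]

    plantedL <- maskCenterVoxel(anatomy$hipHeadL)
    plantedR <- maskCenterVoxel(anatomy$hipHeadR)
    r <- spec@rTarget
    for (pv in list(plantedL, plantedR)) {
        lin <- pv[1] + (pv[2] - 1L) * d[1] + (pv[3] - 1L) * d[1] * d[2]
        row <- match(lin, brainIdx)
        mat[row, ] <- r * latent + sqrt(1 - r^2) * mat[row, ]
    }

    mat <- spec@noiseSd * mat +
        matrix(confound, nb, nt, byrow = TRUE) + spec@baseline

    data <- array(0, c(d, nt))
    step <- prod(d)
    for (t in seq_len(nt))
        data[brainIdx + (t - 1L) * step] <- mat[, t]

    list(bold = boldImage(data, spec@voxelSize, spec@TR),
         truth = list(plantedL = plantedL, plantedR = plantedR,
                      latent = latent,
                      regions = anatomy[c("hipHeadL", "hipHeadR", "pccGm",
                                          "dmnNetwork")]),
         physio = physioTrace(phC, phR))
}

#' Simulate per-subject motion summaries
#'
#' Draws slice-wise mean and maximum head-motion estimates (mm) for a cohort,
#' optionally planting a fraction of high-motion outliers at
#' `outlierSd` base standard deviations above the base mean, so the
#' 2.5-SD exclusion rule can be exercised against known ground truth.
#'
#' @param nSubjects number of subjects (>= 3).
#' @param outlierFrac fraction of subjects planted as outliers.
#' @param outlierSd outlier offset, in multiples of the base sd.
#' @param baseMeanMm,baseSdMm base distribution of mean motion (mm).
#' @param seed integer RNG seed.
#' @return data.frame: `subject`, `meanMotion`, `maxMotion`,
#'   `plantedOutlier`.
#' @export
simulateMotion <- function(nSubjects, outlierFrac = 0, outlierSd = 10,
                           baseMeanMm = 0.12, baseSdMm = 0.03, seed = 1L) {
    if (nSubjects < 3L)
        stop("need at least 3 subjects")
    withr::local_seed(as.integer(seed))
    meanMot <- abs(rnorm(nSubjects, baseMeanMm, baseSdMm))
    maxMot <- meanMot * runif(nSubjects, 1.5, 3)
    planted <- rep(FALSE, nSubjects)
    nOut <- round(outlierFrac * nSubjects)
    if (nOut > 0) {
        out <- sample.int(nSubjects, nOut)
        planted[out] <- TRUE
        meanMot[out] <- baseMeanMm + outlierSd * baseSdMm
        maxMot[out] <- meanMot[out] * 2.5
    }
    data.frame(subject = sprintf("sub%02d", seq_len(nSubjects)),
               meanMotion = meanMot, maxMotion = maxMot,
               plantedOutlier = planted)
}

defaultCohortMeasures <- function() {
    # per-measure group means and sds (mm3), DS and HC columns
    measures <- c("icv",
                  "erc_l", "sub_l", "ca1_l", "ca2_l", "ca3_l", "dg_l", "tail_l",
                  "erc_r", "sub_r", "ca1_r", "ca2_r", "ca3_r", "dg_r", "tail_r")
    meansDS <- c(1204000, 289, 563, 1021, 14, 13, 571, 110,
                 323, 483, 1220, 5, 5, 616, 86)
    meansHC <- c(1421000, 368, 653, 1446, 25, 25, 810, 156,
                 371, 555, 1614, 11, 11, 844, 121)
    sdsDS <- c(96000, 112, 91, 137, 8, 8, 99, 27,
               108, 70, 151, 3, 3, 112, 19)
    sdsHC <- c(114000, 53, 75, 153, 15, 15, 116, 27,
               61, 67, 127, 7, 7, 120, 26)
    list(means = data.frame(measure = measures, DS = meansDS, HC = meansHC),
         sds = data.frame(measure = measures, DS = sdsDS, HC = sdsHC))
}

#' Specify a synthetic volumetric cohort
#'
#' Builds a validated [CohortSpec-class]. Default group means and sds follow
#' published group-averaged hippocampal subfield volumes for a trisomy-21
#' (DS) cohort and age-matched healthy controls (HC); ICV defaults are
#' derived from the same table's percent-of-ICV columns. CA2/CA3 means are
#' the small remainders CAt - CA1 split evenly (they are carried only to
#' form the CA-total composite).
#'
#' @param nPerGroup subjects per group, named `c(DS = , HC = )`.
#' @param means,sds optional replacement data.frames (columns `measure`,
#'   `DS`, `HC`).
#' @param ageRange age range in years.
#' @param maleFraction male fraction per group, named.
#' @param volumeCorrelation shared-factor correlation between measures
#'   within subject, in `[0, 1)`.
#' @param seed integer RNG seed.
#' @return A [CohortSpec-class] object.
#' @export
cohortSpec <- function(nPerGroup = c(DS = 34L, HC = 27L),
                       means = NULL, sds = NULL,
                       ageRange = c(15, 35),
                       maleFraction = c(DS = 0.65, HC = 0.63),
                       volumeCorrelation = 0, seed = 1L) {
    def <- defaultCohortMeasures()
    new("CohortSpec",
        nPerGroup = stats::setNames(as.integer(nPerGroup), names(nPerGroup)),
        means = if (is.null(means)) def$means else means,
        sds = if (is.null(sds)) def$sds else sds,
        ageRange = as.numeric(ageRange),
        maleFraction = maleFraction,
        volumeCorrelation = as.numeric(volumeCorrelation),
        seed = as.integer(seed))
}

#' Simulate a cohort volume table
#'
#' Draws one row per subject with group label, age, sex, ICV and left/right
#' subfield volumes from per-group normal distributions truncated at zero.
#' With `volumeCorrelation > 0` a shared per-subject standard-normal factor
#' induces that correlation between all volume measures of a subject.
#' Deterministic given the spec's seed.
#'
#' @param spec a [CohortSpec-class].
#' @return data.frame with columns `id`, `group`, `age`, `sex`, `icv`, and
#'   the 14 subfield columns (`erc_l` ... `tail_r`), volumes in mm3.
#' @seealso [deriveComposites()], [icvCorrect()]
#' @export
simulateCohortVolumes <- function(spec) {
    validObject(spec)
    withr::local_seed(spec@seed)
    rho <- spec@volumeCorrelation
    rows <- list()
    for (g in names(spec@nPerGroup)) {
        n <- spec@nPerGroup[[g]]
        mu <- spec@means[[g]]
        sd <- spec@sds[[g]]
        age <- round(runif(n, spec@ageRange[1], spec@ageRange[2]), 1)
        sex <- ifelse(runif(n) < spec@maleFraction[[g]], "M", "F")
        shared <- rnorm(n)
        vals <- matrix(NA_real_, n, length(mu))
        for (j in seq_along(mu)) {
            eps <- rnorm(n)
            v <- mu[j] + sd[j] * (sqrt(rho) * shared + sqrt(1 - rho) * eps)
            while (any(v <= 0))  # truncate at 0 by redrawing
                v[v <= 0] <- mu[j] + sd[j] * (sqrt(rho) * shared[v <= 0] +
                                              sqrt(1 - rho) * rnorm(sum(v <= 0)))
            vals[, j] <- v
        }
        colnames(vals) <- spec@means$measure
        rows[[g]] <- data.frame(id = sprintf("%s%02d", g, seq_len(n)),
                                group = g, age = age, sex = sex,
                                vals, check.names = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
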