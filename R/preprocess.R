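# Functional post-processing chain: drop initial volumes -> physiological
# confound regression -> spatial smoothing -> linear detrend -> temporal
# low-pass; plus the 2.5-SD motion-based subject exclusion rule.

# flatten a BoldImage to an nt x nvox matrix and back
boldToMatrix <- function(bold) {
    d <- dim(bold@data)
    t(matrix(bold@data, prod(d[1:3]), d[4]))
}

matrixToBold <- function(mat, template) {
    d <- dim(template@data)
    d[4] <- nrow(mat)
    boldImage(array(t(mat), d), template@voxelSize, template@TR)
}

#' Drop initial volumes
#'
#' Removes the first `k` volumes of a functional time series (the
#' steady-state dummy scans), leaving the remaining data untouched.
#'
#' @param bold a [BoldImage-class].
#' @param k number of leading volumes to remove (default 4).
#' @return A [BoldImage-class] with `nt - k` volumes.
#' @export
dropInitialVolumes <- function(bold, k = 4L) {
    nt <- dim(bold@data)[4]
    if (k < 0) stop("k must be non-negative")
    if (k >= nt)
        stop(sprintf("cannot drop %d volumes from a %d-volume series", k, nt))
    if (k == 0L) return(bold)
    boldImage(bold@data[, , , (k + 1):nt, drop = FALSE],
              bold@voxelSize, bold@TR)
}

#' Build RETROICOR-style physiological regressors
#'
#' Fourier expansion of the measured cardiac and respiratory phases:
#' `sin(m * phi)` and `cos(m * phi)` for `m = 1..order`, for each trace,
#' giving `4 * order` columns.
#'
#' @param physio a [PhysioTrace-class].
#' @param order Fourier order (>= 1, default 2).
#' @return Numeric matrix, `nt x (4 * order)`, with descriptive column names.
#' @export
buildPhysioRegressors <- function(physio, order = 2L) {
    if (order < 1L) stop("order must be >= 1")
    cols <- list()
    for (m in seq_len(order)) {
        cols[[sprintf("card_sin%d", m)]] <- sin(m * physio@cardiac)
        cols[[sprintf("card_cos%d", m)]] <- cos(m * physio@cardiac)
        cols[[sprintf("resp_sin%d", m)]] <- sin(m * physio@respiratory)
        cols[[sprintf("resp_cos%d", m)]] <- cos(m * physio@respiratory)
    }
    do.call(cbind, cols)
}

#' Regress confounds out of a BOLD series
#'
#' Per voxel, fits ordinary least squares of the time series on the supplied
#' regressors (plus an intercept) and returns the residuals with the voxel
#' mean added back. Residuals are orthogonal to every regressor column.
#'
#' @param bold a [BoldImage-class].
#' @param regressors numeric matrix with `nt` rows.
#' @return A [BoldImage-class] of the same dimensions.
#' @export
regressConfounds <- function(bold, regressors) {
    regressors <- as.matrix(regressors)
    nt <- dim(bold@data)[4]
    if (nrow(regressors) != nt)
        stop("regressor rows must match the number of volumes")
    X <- cbind(intercept = 1, regressors)
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
        dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
        stop("rank-deficient confound design; collinear columns: ",
             paste(dropped, collapse = ", "))
    }
    Y <- boldToMatrix(bold)                  # nt x nvox
    resid <- qr.resid(qrX, Y)
    out <- resid + matrix(colMeans(Y), nt, ncol(Y), byrow = TRUE)
    matrixToBold(out, bold)
}

# 1D convolution along one axis of a 3D array with a symmetric kernel and
# half-sample reflective boundary (sum-preserving for symmetric kernels).
convolveAxis <- function(vol, kernel, axis) {
    r <- (length(kernel) - 1L) / 2L
    perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
    v <- aperm(vol, perm)
    d <- dim(v)
    m <- matrix(v, d[1], d[2] * d[3])
    n <- d[1]
    refl <- function(i) ifelse(i < 1L, 1L - i, ifelse(i > n, 2L * n + 1L - i, i))
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(kernel)) {
        off <- j - r - 1L
        out <- out + kernel[j] * m[refl(seq_len(n) + off), , drop = FALSE]
    }
    res <- array(out, d)
    aperm(res, order(perm))
}

#' Spatially smooth each volume
#'
#' Per-volume separable Gaussian smoothing. The FWHM is specified in mm and
#' converted per axis to a sigma in voxels,
#' `sigma = fwhm / (2 * sqrt(2 * log(2))) / voxelSize`. Boundaries are
#' handled by half-sample reflection, which preserves the volume-wise mean.
#'
#' @param bold a [BoldImage-class].
#' @param fwhmMm full width at half maximum of the Gaussian kernel (mm);
#'   0 returns the input unchanged.
#' @return A smoothed [BoldImage-class].
#' @export
spatialSmooth <- function(bold, fwhmMm = 2.0) {
    if (fwhmMm < 0) stop("fwhm must be non-negative")
    if (fwhmMm == 0) return(bold)
    sigmaVox <- fwhmMm / (2 * sqrt(2 * log(2))) / bold@voxelSize
    kernels <- lapply(sigmaVox, gaussianKernel1d)
    d <- dim(bold@data)
    out <- bold@data
    for (t in seq_len(d[4])) {
        vol <- out[, , , t]
        for (ax in 1:3)
            vol <- convolveAxis(vol, kernels[[ax]], ax)
        out[, , , t] <- vol
    }
    boldImage(out, bold@voxelSize, bold@TR)
}

# least-squares polynomial detrend of the columns of an nt x k matrix
detrendMatrix <- function(m, order = 1L) {
    nt <- nrow(m)
    if (nt < 3L) stop("need at least 3 time points to detrend")
    tt <- seq_len(nt)
    X <- stats::poly(tt, degree = order, raw = FALSE)
    X <- cbind(1, X)
    qr.resid(qr(X), m)
}

#' Temporally detrend a series or image
#'
#' Subtracts the per-voxel ordinary-least-squares polynomial trend in time
#' (default linear), leaving each voxel's residual series with zero mean and
#' zero fitted slope.
#'
#' @param x a numeric vector, an `nt x k` matrix (time in rows), or a
#'   [BoldImage-class].
#' @param order polynomial order (default 1, linear).
#' @return Same shape as the input.
#' @export
temporalDetrend <- function(x, order = 1L) {
    if (is(x, "BoldImage"))
        return(matrixToBold(detrendMatrix(boldToMatrix(x), order), x))
    if (is.matrix(x))
        return(detrendMatrix(x, order))
    as.numeric(detrendMatrix(matrix(x, ncol = 1), order))
}

#' Temporal low-pass filter (ideal DFT cutoff)
#'
#' Removes fluctuations above `cutoffHz` per voxel by zeroing discrete
#' Fourier coefficients at frequencies strictly greater than the cutoff and
#' inverting the transform. Retained frequencies (including DC) are
#' untouched, so the filter is idempotent and exactly passes on-grid
#' sinusoids at or below the cutoff.
#'
#' @param x a numeric vector, an `nt x k` matrix, or a [BoldImage-class].
#' @param cutoffHz cutoff frequency in Hz (default 0.08); must be below the
#'   Nyquist frequency `1 / (2 * TR)`.
#' @param TR sampling interval in seconds (taken from the image when `x` is
#'   a [BoldImage-class]).
#' @return Same shape as the input.
#' @export
lowpassFilter <- function(x, cutoffHz = 0.08, TR = NULL) {
    if (is(x, "BoldImage")) {
        m <- lowpassMatrix(boldToMatrix(x), cutoffHz, x@TR)
        return(matrixToBold(m, x))
    }
    if (is.null(TR)) stop("TR is required for vector/matrix input")
    if (is.matrix(x))
        return(lowpassMatrix(x, cutoffHz, TR))
    as.numeric(lowpassMatrix(matrix(x, ncol = 1), cutoffHz, TR))
}

lowpassMatrix <- function(m, cutoffHz, TR) {
    nyquist <- 1 / (2 * TR)
    if (cutoffHz >= nyquist)
        stop(sprintf("cutoff %.4g Hz is not below Nyquist %.4g Hz",
                     cutoffHz, nyquist))
    nt <- nrow(m)
    k <- seq_len(nt) - 1
    freq <- pmin(k, nt - k) / (nt * TR)
    keep <- freq <= cutoffHz
    co <- stats::mvfft(m)
    co[!keep, ] <- 0
    Re(stats::mvfft(co, inverse = TRUE)) / nt
}

#' Exclude subjects by motion
#'
#' Applies the one-pass, upper-tail exclusion rule: a subject is excluded if
#' its mean motion exceeds `groupMean(mean) + kSd * sd(mean)` or its maximum
#' motion exceeds `groupMean(max) + kSd * sd(max)` (sample sd, n - 1
#' denominator; thresholds are not recomputed after removal).
#'
#' @param summaries data.frame with columns `subject`, `meanMotion`,
#'   `maxMotion`.
#' @param kSd threshold multiplier (default 2.5).
#' @return list with data.frames `kept` and `excluded`, and the numeric
#'   `thresholds` used.
#' @export
excludeByMotion <- function(summaries, kSd = 2.5) {
    if (nrow(summaries) < 3L)
        stop("need at least 3 subjects to estimate motion thresholds")
    if (any(summaries$meanMotion > summaries$maxMotion))
        stop("mean motion cannot exceed max motion")
    thrMean <- mean(summaries$meanMotion) + kSd * sd(summaries$meanMotion)
    thrMax <- mean(summaries$maxMotion) + kSd * sd(summaries$maxMotion)
    bad <- summaries$meanMotion > thrMean | summaries$maxMotion > thrMax
    list(kept = summaries[!bad, , drop = FALSE],
         excluded = summaries[bad, , drop = FALSE],
         thresholds = c(mean = thrMean, max = thrMax))
}

#' Run the full post-processing chain
#'
#' Applies, in fixed order: volume dropping, physiological confound
#' regression, spatial smoothing, temporal detrending, and temporal
#' low-pass filtering.
#'
#' @param bold a [BoldImage-class].
#' @param physio a [PhysioTrace-class] covering the *original* (pre-drop)
#'   series; the first `kDrop` entries are discarded along with the volumes.
#' @param config a [PipelineConfig-class] (see [pipelineConfig()]).
#' @return A preprocessed [BoldImage-class].
#' @export
preprocessBold <- function(bold, physio, config = pipelineConfig()) {
    b <- dropInitialVolumes(bold, config@kDrop)
    keep <- (config@kDrop + 1):length(physio@cardiac)
    ph <- physioTrace(physio@cardiac[keep], physio@respiratory[keep])
    reg <- buildPhysioRegressors(ph, config@physioOrder)
    b <- regressConfounds(b, reg)
    b <- spatialSmooth(b, config@fwhmMm)
    b <- temporalDetrend(b, config@detrendOrder)
    lowpassFilter(b, config@cutoffHz)
}
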