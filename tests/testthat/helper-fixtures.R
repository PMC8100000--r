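# Shared small fixtures, built once per test run.

defaultAnatomy <- makePhantomAnatomy(phantomSpec())

# tiny BOLD image from a matrix of voxel series (nt x nvox laid on a grid)
toyBold <- function(seriesMatrix, dims, voxelSize = c(1, 1, 1), TR = 1) {
    stopifnot(prod(dims) == ncol(seriesMatrix))
    boldImage(array(t(seriesMatrix), c(dims, nrow(seriesMatrix))),
              voxelSize, TR)
}

# confound-regressed + detrended series for the seed search on a phantom,
# cropped to a bounding box containing the hippocampal and PCC regions
# (voxelwise operations are unaffected by cropping)
searchImage <- function(sim, anatomy, kDrop = 4L, order = 2L) {
    crop <- function(a) a[, 12:30, 8:17, drop = FALSE]
    d <- sim$bold@data[, 12:30, 8:17, , drop = FALSE]
    b <- dropInitialVolumes(boldImage(d, sim$bold@voxelSize, sim$bold@TR),
                            kDrop)
    nt0 <- dim(sim$bold@data)[4]
    keep <- (kDrop + 1):nt0
    ph <- physioTrace(sim$physio@cardiac[keep], sim$physio@respiratory[keep])
    clean <- regressConfounds(b, buildPhysioRegressors(ph, order))
    list(bold = temporalDetrend(clean),
         hipL = crop(anatomy$hipHeadL), hipR = crop(anatomy$hipHeadR),
         conj = crop(conjunctionMask(anatomy$dmnNetwork, anatomy$pccGm)),
         plantedL = sim$truth$plantedL - c(0L, 11L, 7L),
         plantedR = sim$truth$plantedR - c(0L, 11L, 7L))
}
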