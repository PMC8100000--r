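# Seed selection and connectivity map creation.

test_that("conjunction mask is the voxelwise AND", {
    a <- array(FALSE, c(4, 4, 2)); b <- a
    a[1:3, 1, 1] <- TRUE
    b[2:4, 1, 1] <- TRUE
    expect_equal(which(conjunctionMask(a, b)), which(a & b))
    expect_identical(conjunctionMask(a, a), a)
    disj <- array(FALSE, c(4, 4, 2)); disj[4, 4, 2] <- TRUE
    expect_warning(conjunctionMask(a, disj), "empty")
    expect_error(conjunctionMask(a, array(FALSE, c(3, 3, 3))), "grid")
})

test_that("cross-correlation matrix holds voxel-pair Pearson r", {
    set.seed(31)
    nt <- 30
    s <- rnorm(nt)
    m <- cbind(s, -s, rnorm(nt), rep(1, nt))
    b <- toyBold(m, c(4, 1, 1))
    ra <- array(FALSE, c(4, 1, 1)); ra[1:2, 1, 1] <- TRUE
    rb <- array(FALSE, c(4, 1, 1)); rb[c(1, 3, 4), 1, 1] <- TRUE
    expect_warning(cc <- crossCorrelateRegions(b, ra, rb), "zero-variance")
    expect_equal(cc$corr[1, 1], 1)          # voxel vs itself
    expect_equal(cc$corr[2, 1], -1)         # negated series
    expect_true(is.na(cc$corr[1, 3]))       # constant voxel flagged
    expect_error(crossCorrelateRegions(b, array(FALSE, c(4, 1, 1)), rb),
                 "nonempty")
})

test_that("seed voxel selection equals the brute-force argmax", {
    m <- matrix(c(0.1, 0.2, 0.9, 0.0), 2, 2, byrow = TRUE)
    expect_equal(selectSeedVoxel(m), 2)
    # identical rows: lowest-index tie rule
    ties <- matrix(0.4, 5, 3)
    expect_equal(selectSeedVoxel(ties), 1)
    set.seed(17)
    for (i in 1:200) {
        rmat <- matrix(runif(20 * 30, -1, 1), 20, 30)
        rmat[sample(length(rmat), 25)] <- NA  # undefined entries ignored
        expect_equal(selectSeedVoxel(rmat), bruteArgmaxRow(rmat))
    }
    expect_error(selectSeedVoxel(matrix(NA_real_, 2, 2)), "undefined")
    # mean aggregation alternative
    mm <- matrix(c(0.9, -0.8, 0.1, 0.2), 2, 2, byrow = TRUE)
    expect_equal(selectSeedVoxel(mm, "max"), 1)
    expect_equal(selectSeedVoxel(mm, "mean"), 2)
})

test_that("in-plane ROI is the 3x3 axial neighborhood", {
    mask <- array(TRUE, c(20, 20, 10))
    roi <- makeInplaneROI(c(10, 10, 5), mask)
    expect_equal(nrow(roiMembers(roi)), 9)
    expect_setequal(roiMembers(roi)[, 1], rep(9:11, 3))
    expect_true(all(roiMembers(roi)[, 3] == 5))
    expect_equal(roiCenter(roi), c(10L, 10L, 5L))
    expect_error(makeInplaneROI(c(1, 10, 5), mask), "boundary")
    # members outside the hippocampal mask are kept with a warning
    edge <- array(FALSE, c(20, 20, 10))
    edge[10:12, 10:12, 5] <- TRUE
    expect_warning(roiE <- makeInplaneROI(c(10, 10, 5), edge), "5 ROI member")
    expect_equal(nrow(roiMembers(roiE)), 9)
    expect_error(makeInplaneROI(c(5, 5, 5), edge), "not inside")
})

test_that("seed series is the detrended 9-voxel mean", {
    nt <- 4
    mask <- array(TRUE, c(3, 3, 1))
    set.seed(8)
    m <- matrix(rnorm(nt * 9), nt, 9)
    b <- toyBold(m, c(3, 3, 1))
    roi <- makeInplaneROI(c(2, 2, 1), mask)
    s <- seedTimeseries(b, roi)
    # hand-computed: mean across the 9 voxels, then OLS line removed
    mu <- rowMeans(m)
    expect_equal(s, unname(residuals(lm(mu ~ seq_len(nt)))), tolerance = 1e-10)
    # constant voxels give a zero series
    bc <- toyBold(matrix(2, nt, 9), c(3, 3, 1))
    expect_equal(seedTimeseries(bc, roi), rep(0, nt))
})

test_that("voxelwise connectivity reproduces seed self-correlation", {
    set.seed(41)
    nt <- 40
    m <- matrix(rnorm(nt * 8), nt, 8)
    b <- toyBold(m, c(2, 2, 2))
    brain <- array(TRUE, c(2, 2, 2))
    seed <- temporalDetrend(m[, 3])
    rmap <- voxelwiseConnectivity(b, seed, brain)
    expect_equal(mapValues(rmap)[3], 1)  # the seed's own voxel
    # anti-correlated voxel
    m2 <- m; m2[, 5] <- -m[, 3]
    rmap2 <- voxelwiseConnectivity(toyBold(m2, c(2, 2, 2)), seed, brain)
    expect_equal(mapValues(rmap2)[5], -1)
    expect_error(voxelwiseConnectivity(b, rep(0, nt), brain), "zero variance")
})

test_that("r-to-t conversion follows the closed form", {
    mask <- array(TRUE, c(3, 1, 1))
    rmap <- statMap(array(c(0, 0.5, -0.5), c(3, 1, 1)), mask, "r")
    tmap <- rToT(rmap, 128)
    expect_equal(tmap@df, 126)
    expect_equal(mapValues(tmap)[1], 0)
    expect_equal(mapValues(tmap)[2], 0.5 * sqrt(126) / sqrt(0.75),
                 tolerance = 1e-10)
    expect_equal(mapValues(tmap)[2], 6.4807, tolerance = 1e-4)
    expect_equal(mapValues(tmap)[3], -mapValues(tmap)[2])  # antisymmetry
    sat <- statMap(array(c(1, 0.2, 0), c(3, 1, 1)), mask, "r")
    expect_warning(tm <- rToT(sat, 10), "infinite")
    expect_true(is.infinite(mapValues(tm)[1]))
})

test_that("map normalization yields exact zero mean and unit sd", {
    mask <- array(TRUE, c(3, 1, 1))
    z <- normalizeMap(statMap(array(c(1, 2, 3), c(3, 1, 1)), mask, "t",
                              df = 10))
    expect_equal(as.numeric(mapValues(z)), c(-1, 0, 1))
    expect_error(normalizeMap(statMap(array(2, c(3, 1, 1)), mask, "t")),
                 "zero-variance")
    # affine invariance of the output distribution
    set.seed(3)
    mask2 <- array(TRUE, c(5, 4, 2))
    vals <- array(rnorm(40), c(5, 4, 2))
    z1 <- normalizeMap(statMap(vals, mask2, "t"))
    z2 <- normalizeMap(statMap(3 * vals + 7, mask2, "t"))
    expect_equal(mapValues(z1), mapValues(z2), tolerance = 1e-12)
    v <- mapValues(z1)[mask2]
    expect_lt(abs(mean(v)), 1e-10)
    expect_lt(abs(sd(v) - 1), 1e-10)
})

test_that("the planted voxel wins the hippocampus-PCC search", {
    anat <- defaultAnatomy
    hits <- vapply(1:30, function(s) {
        spec <- phantomSpec(rTarget = 0.8, nVolumes = 128L, seed = s + 500L)
        sim <- simulateBold(anat, spec)
        se <- searchImage(sim, anat)
        cc <- crossCorrelateRegions(se$bold, se$hipL, se$conj)
        sel <- selectSeedVoxel(cc)
        identical(attr(sel, "voxel"), se$plantedL)
    }, logical(1))
    expect_gte(mean(hits), 0.95)
})

test_that("hemisphere pipelines are independent", {
    anat <- defaultAnatomy
    spec <- phantomSpec(nVolumes = 48L, seed = 77L)
    sim <- simulateBold(anat, spec)
    se <- searchImage(sim, anat)
    ccL <- crossCorrelateRegions(se$bold, se$hipL, se$conj)
    # scramble the right-hemisphere hippocampus data; left result unchanged
    scr <- se$bold
    idxR <- which(se$hipR)
    d <- dim(scr@data)
    m <- hippoconn:::boldToMatrix(scr)
    m[, idxR] <- m[sample(nrow(m)), idxR]
    scr2 <- hippoconn:::matrixToBold(m, scr)
    ccL2 <- crossCorrelateRegions(scr2, se$hipL, se$conj)
    expect_identical(selectSeedVoxel(ccL), selectSeedVoxel(ccL2))
    expect_equal(ccL$corr, ccL2$corr)
})
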