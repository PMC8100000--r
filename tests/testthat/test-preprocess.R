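# Post-processing chain operators.

test_that("dropInitialVolumes removes exactly the leading volumes", {
    m <- matrix(rnorm(132 * 4), 132, 4)
    b <- toyBold(m, c(2, 2, 1))
    d <- dropInitialVolumes(b, 4)
    expect_equal(nVolumes(d), 128)
    expect_equal(d@data[1, 1, 1, ], m[5:132, 1])
    expect_identical(dropInitialVolumes(b, 0), b)
    small <- toyBold(matrix(rnorm(12), 3, 4), c(2, 2, 1))
    expect_error(dropInitialVolumes(small, 4), "cannot drop")
})

test_that("physio regressors are the Fourier expansion of the phases", {
    nt <- 50
    ph <- physioTrace(rep(0, nt), rep(0, nt))
    X <- buildPhysioRegressors(ph, 2)
    expect_equal(ncol(X), 8)
    expect_true(all(X[, grepl("cos", colnames(X))] == 1))
    expect_true(all(X[, grepl("sin", colnames(X))] == 0))
    # uniform full-cycle phase: near-orthogonal columns
    phi <- 2 * pi * (0:(nt - 1)) / nt
    Xu <- buildPhysioRegressors(physioTrace(phi, (3 * phi) %% (2 * pi)), 2)
    G <- crossprod(scale(Xu, scale = FALSE))
    offdiag <- G[upper.tri(G)]
    expect_lt(max(abs(offdiag)) / nt, 0.05)
    expect_error(buildPhysioRegressors(ph, 0), "order")
})

test_that("confound regression leaves residuals orthogonal to the design", {
    set.seed(21)
    nt <- 40
    reg <- cbind(a = rnorm(nt), b = rnorm(nt))
    m <- matrix(rnorm(nt * 6), nt, 6)
    m[, 3] <- reg[, 1]  # voxel equal to a regressor column
    b <- toyBold(m, c(3, 2, 1))
    out <- regressConfounds(b, reg)
    res <- hippoconn:::boldToMatrix(out)
    centered <- scale(res, scale = FALSE)
    expect_lt(max(abs(crossprod(centered, reg))) /
                  (max(abs(reg)) * max(abs(centered), 1)), 1e-8)
    expect_equal(sd(centered[, 3]), 0, tolerance = 1e-10)
    expect_equal(colMeans(res), colMeans(m))  # voxel means restored
    expect_error(regressConfounds(b, cbind(reg, zero = 0)), "collinear")
})

test_that("confound regression removes the planted physiological signal", {
    spec <- phantomSpec(nVolumes = 64L, seed = 13L)
    anat <- defaultAnatomy
    sim <- simulateBold(anat, spec)
    reg <- buildPhysioRegressors(sim$physio, 2)
    clean <- regressConfounds(sim$bold, reg)
    conf <- spec@cardiacAmp * cos(sim$physio@cardiac) +
        spec@respAmp * cos(sim$physio@respiratory)
    # probe an arbitrary in-brain, non-planted voxel
    v <- which(anat$brain & !anat$pccGm, arr.ind = TRUE)[200, ]
    before <- cor(sim$bold@data[v[1], v[2], v[3], ], conf)
    after <- cor(clean@data[v[1], v[2], v[3], ], conf)
    expect_gt(abs(before), 0.15)
    expect_lt(abs(after), 0.05)
})

test_that("Gaussian smoothing matches the closed form and preserves means", {
    d <- array(0, c(17, 17, 17, 2))
    d[9, 9, 9, 1] <- 1
    d[, , , 2] <- 3  # constant volume
    b <- boldImage(d, voxelSize = c(1, 1, 1), TR = 1)
    s <- spatialSmooth(b, 2)
    sigma <- 2 / (2 * sqrt(2 * log(2)))
    expect_equal(sigma, 0.8493, tolerance = 1e-4)
    # separable 3D Gaussian: value on the x axis through the impulse
    prof <- s@data[9:13, 9, 9, 1]
    closed <- dnorm(0:4, 0, sigma) * dnorm(0, 0, sigma)^2
    expect_lt(max(abs(prof - closed)), 1e-3)
    expect_equal(mean(s@data[, , , 1]), mean(d[, , , 1]), tolerance = 1e-6)
    expect_equal(s@data[, , , 2], d[, , , 2])        # constant unchanged
    expect_identical(spatialSmooth(b, 0), b)          # fwhm 0 = identity
    expect_error(spatialSmooth(b, -1), "non-negative")
})

test_that("detrending removes exactly the least-squares line", {
    expect_equal(temporalDetrend(c(1, 2, 3, 4)), rep(0, 4))
    expect_equal(temporalDetrend(rep(5, 10)), rep(0, 10))
    # line + sinusoid: result equals the sinusoid minus its own fitted line
    nt <- 50
    tt <- seq_len(nt)
    sine <- sin(2 * pi * tt / 12)
    x <- 3 + 0.2 * tt + sine
    fit <- lm(sine ~ tt)
    expect_equal(temporalDetrend(x), unname(residuals(fit)), tolerance = 1e-10)
    expect_error(temporalDetrend(c(1, 2)), "3 time points")
})

test_that("low-pass passes retained on-grid frequencies and kills the rest", {
    nt <- 128; TR <- 2.8
    tt <- (0:(nt - 1)) * TR
    lo <- sin(2 * pi * (7 / (nt * TR)) * tt)    # 0.0195 Hz, on-grid
    hi <- sin(2 * pi * (36 / (nt * TR)) * tt)   # 0.1004 Hz, on-grid
    ylo <- lowpassFilter(lo, 0.08, TR = TR)
    yhi <- lowpassFilter(hi, 0.08, TR = TR)
    expect_lt(sqrt(mean((ylo - lo)^2)) / sqrt(mean(lo^2)), 1e-6)
    expect_lt(sqrt(mean(yhi^2)) / sqrt(mean(hi^2)), 1e-6)
    cst <- rep(7, nt)
    expect_equal(lowpassFilter(cst, 0.08, TR = TR), cst)  # DC retained
    # idempotent
    x <- rnorm(nt)
    once <- lowpassFilter(x, 0.08, TR = TR)
    twice <- lowpassFilter(once, 0.08, TR = TR)
    expect_equal(twice, once, tolerance = 1e-10)
    expect_error(lowpassFilter(x, 0.2, TR = TR), "Nyquist")
})

test_that("motion exclusion applies the k-sd rule once, upper tail only", {
    mk <- function(means) data.frame(subject = seq_along(means),
                                     meanMotion = means,
                                     maxMotion = means)
    # worked example: threshold 1.5 + 2.5 * 1.5811 = 5.453 -> 6 excluded
    r <- excludeByMotion(mk(c(rep(1, 9), 6)))
    expect_equal(r$excluded$subject, 10)
    expect_equal(unname(r$thresholds["mean"]), 1.5 + 2.5 * sd(c(rep(1, 9), 6)))
    # worked example: threshold 2.8 + 2.5 * 4.025 = 12.86 -> none excluded
    r2 <- excludeByMotion(mk(c(1, 1, 1, 1, 10)))
    expect_equal(nrow(r2$excluded), 0)
    # all equal: sd = 0, none excluded
    r3 <- excludeByMotion(mk(rep(2, 5)))
    expect_equal(nrow(r3$excluded), 0)
    # permutation invariance of the excluded set
    set.seed(5)
    means <- c(rnorm(12, 1, 0.1), 4)
    perm <- sample(13)
    a <- excludeByMotion(mk(means))
    b <- excludeByMotion(mk(means[perm]))
    expect_setequal(a$excluded$meanMotion, b$excluded$meanMotion)
    expect_error(excludeByMotion(mk(c(1, 2))), "3 subjects")
})
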