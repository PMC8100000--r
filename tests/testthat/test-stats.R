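# t-tests, correlation, FDR, interaction regression.

test_that("unpaired t matches the pooled-variance textbook formula", {
    r <- unpairedT(c(1, 2, 3), c(1, 2, 3))
    expect_equal(r$statistic, 0)
    expect_equal(r$p, 1)
    r2 <- unpairedT(c(1, 2, 3), c(2, 3, 4))
    expect_equal(r2$statistic, -1.2247, tolerance = 1e-4)
    expect_equal(r2$df, 4)
    set.seed(14)
    for (i in 1:50) {
        x <- rnorm(sample(3:20, 1)); y <- rnorm(sample(3:20, 1), 0.3)
        got <- unpairedT(x, y)
        want <- pooledTOracle(x, y)
        expect_equal(got$statistic, want$t, tolerance = 1e-12)
        expect_equal(got$df, want$df)
        expect_equal(got$p, want$p, tolerance = 1e-12)
    }
    expect_error(unpairedT(c(1, 1), c(1, 1)), "zero pooled variance")
    expect_error(unpairedT(1, c(1, 2)), "n >= 2")
})

test_that("paired t works on differences with df = n - 1", {
    x <- c(2, 3, 4, 1); y <- x - c(1, 1, 1, -1)   # diffs 1,1,1,-1
    r <- pairedT(x, y)
    expect_equal(r$statistic, 1.0)
    expect_equal(r$df, 3)
    r2 <- pairedT(y, x)
    expect_equal(r2$statistic, -1.0)               # sign flip
    expect_error(pairedT(x, x), "zero variance")
    expect_error(pairedT(1:3, 1:4), "equal length")
})

test_that("Pearson correlation shares the r-to-t mapping", {
    x <- c(1, 2, 3, 5, 8)
    r <- pearsonCorr(x, 2 * x + 1)
    expect_equal(r$r, 1)
    set.seed(23)
    x <- rnorm(30); y <- rnorm(30)
    got <- pearsonCorr(x, y)
    rr <- cor(x, y)
    tt <- rr * sqrt(28) / sqrt(1 - rr^2)
    expect_equal(got$p, 2 * pt(-abs(tt), 28), tolerance = 1e-12)
    # under independence r is near zero for large n
    set.seed(24)
    big <- pearsonCorr(rnorm(2000), rnorm(2000))
    expect_lt(abs(big$r), 0.07)
    expect_error(pearsonCorr(rep(1, 5), rnorm(5)), "zero variance")
})

test_that("BH FDR follows the step-up rule on worked examples", {
    r <- bhFdr(c(0.001, 0.011, 0.02, 0.04, 0.045), 0.05)
    expect_true(all(r$rejected))         # p_(5) = 0.045 <= 5*0.05/5
    r2 <- bhFdr(c(0.04, 0.2, 0.5), 0.05)
    expect_false(any(r2$rejected))       # 0.04 > 0.05/3
    r3 <- bhFdr(0.03, 0.05)
    expect_true(r3$rejected)             # m = 1 reduces to p <= q
    expect_true(all(r$adjusted >= r$p))
    expect_error(bhFdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH FDR equals the brute-force step-up on random p-vectors", {
    set.seed(55)
    for (i in 1:300) {
        m <- sample(1:50, 1)
        p <- round(runif(m), 3)
        q <- sample(c(0.01, 0.05, 0.1), 1)
        got <- bhFdr(p, q)
        expect_identical(got$rejected, bhStepUpOracle(p, q))
    }
})

test_that("BH rejection set is monotone in q", {
    set.seed(56)
    p <- runif(30)
    prev <- rep(FALSE, 30)
    for (q in c(0.01, 0.05, 0.1, 0.2, 0.5)) {
        cur <- bhFdr(p, q)$rejected
        expect_true(all(prev <= cur))
        prev <- cur
    }
})

test_that("a nominally significant p can fail FDR survival", {
    # one strong and one marginal p in a 5-test family: the marginal test is
    # significant at 0.05 alone but does not survive adjustment
    p <- c(0.0005, 0.04, 0.5, 0.7, 0.9)
    r <- bhFdr(p, 0.05)
    expect_true(r$rejected[1])
    expect_lt(p[2], 0.05)
    expect_false(r$rejected[2])
})

test_that("group comparison of the synthetic cohort mirrors the expected pattern", {
    tab <- icvCorrectTable(deriveComposites(
        simulateCohortVolumes(cohortSpec(seed = 31L))))
    res <- groupCompareTable(tab, c("erc_l", "sub_l", "ca1_l", "cat_l",
                                    "dg_l", "tail_l", "hip_l",
                                    "ca1_r", "dg_r", "hip_r"))
    rej <- res$measure[res$rejected]
    # CA fields, DG, tail and HIP differ between groups after correction ...
    expect_true(all(c("ca1_l", "cat_l", "dg_l", "hip_l", "ca1_r", "dg_r",
                      "hip_r") %in% rej))
    # ... while ERC and SUB (similar %ICV in both groups) do not
    expect_false("erc_l" %in% rej)
    expect_false("sub_l" %in% rej)
})

test_that("interaction regression recovers planted slope differences", {
    age <- c(seq(15, 35, length.out = 30), seq(15, 35, length.out = 30))
    group <- rep(c("HC", "DS"), each = 30)
    # noiseless planted slopes: interaction coefficient is exactly the
    # slope difference (reference level "DS", so HC minus DS)
    value <- ifelse(group == "HC", 10 + 1.0 * age, 5 + 1.7 * age)
    fit <- suppressWarnings(interactionRegression(value, age, group))
    expect_equal(unname(fit$coefficients["interaction"]), 1.0 - 1.7,
                 tolerance = 1e-10)
    # matches the normal-equations oracle
    set.seed(61)
    noisy <- value + rnorm(60)
    fit2 <- interactionRegression(noisy, age, group)
    expect_equal(unname(fit2$coefficients),
                 unname(interactionOracle(noisy, age, group)),
                 tolerance = 1e-10)
    # null: interaction coefficient within 3 se almost always
    set.seed(62)
    cover <- vapply(1:300, function(i) {
        v <- 2 + 0.5 * age + rnorm(60)
        f <- interactionRegression(v, age, group)
        se <- summary(f$fit)$coefficients[4, 2]
        abs(f$coefficients["interaction"]) < 3 * se
    }, logical(1))
    expect_gte(mean(cover), 0.98)
    expect_error(interactionRegression(value, rep(1, 60), group), "variance")
})
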