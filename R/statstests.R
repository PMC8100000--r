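# Statistical machinery: two-sample and paired t-tests, Pearson
# correlation, Benjamini-Hochberg FDR, and the age x group interaction
# regression. Thin, contract-checked wrappers over base R fits so every
# result carries (statistic, df, p, direction) uniformly.

testResult <- function(statistic, df, p, direction) {
    list(statistic = unname(statistic), df = unname(df), p = unname(p),
         direction = direction)
}

#' Unpaired two-sample t-test
#'
#' Student's pooled-variance t-test by default (`equalVar = TRUE`); Welch
#' available via flag. Two-sided p.
#'
#' @param x,y numeric samples, each n >= 2.
#' @param equalVar pool variances (default `TRUE`).
#' @return list: `statistic`, `df`, `p`, `direction` (+1 if `mean(x) >
#'   mean(y)`).
#' @export
unpairedT <- function(x, y, equalVar = TRUE) {
    if (length(x) < 2L || length(y) < 2L)
        stop("each sample needs n >= 2")
    if (sd(x) == 0 && sd(y) == 0)
        stop("zero pooled variance")
    tt <- stats::t.test(x, y, var.equal = equalVar)
    testResult(tt$statistic, tt$parameter, tt$p.value,
               sign(mean(x) - mean(y)))
}

#' Paired t-test
#'
#' Student's t on the paired differences, `df = n - 1`, two-sided p.
#'
#' @param x,y numeric samples of equal length n >= 2 with non-constant
#'   differences.
#' @return list: `statistic`, `df`, `p`, `direction`.
#' @export
pairedT <- function(x, y) {
    if (length(x) != length(y)) stop("samples must have equal length")
    if (length(x) < 2L) stop("need n >= 2 pairs")
    if (sd(x - y) == 0)
        stop("paired differences have zero variance")
    tt <- stats::t.test(x, y, paired = TRUE)
    testResult(tt$statistic, tt$parameter, tt$p.value,
               sign(mean(x - y)))
}

#' Pearson correlation with p-value
#'
#' Pearson r with the usual two-sided p from
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` — the same r-to-t mapping used for
#' the connectivity maps.
#'
#' @param x,y numeric vectors, n >= 3, both with positive variance.
#' @return list: `r`, `p`, `n`.
#' @export
pearsonCorr <- function(x, y) {
    if (length(x) != length(y)) stop("vectors must have equal length")
    if (length(x) < 3L) stop("need n >= 3")
    if (sd(x) == 0 || sd(y) == 0) stop("zero variance input")
    ct <- stats::cor.test(x, y, method = "pearson")
    list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Benjamini-Hochberg FDR
#'
#' Step-up FDR control at level `q`: with the p-values sorted ascending,
#' reject the largest `k` such that `p_(k) <= k * q / m`, and everything
#' smaller. Adjusted p-values by the standard cumulative-minimum formula,
#' capped at 1.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return list: `p` (input), `adjusted`, `rejected` (logical), `q`.
#' @export
bhFdr <- function(p, q = 0.05) {
    if (any(p < 0 | p > 1) || anyNA(p))
        stop("p-values must lie in [0, 1]")
    adj <- stats::p.adjust(p, method = "BH")
    list(p = p, adjusted = adj, rejected = adj <= q, q = q)
}

#' Age x group interaction regression
#'
#' Ordinary least squares of `value ~ group + age + age:group` with the
#' group coded 0/1, testing whether the age slope differs between groups.
#'
#' @param value numeric response.
#' @param age numeric covariate.
#' @param group factor/character with exactly two levels; the first level
#'   (reference) is coded 0.
#' @return list: `coefficients` (intercept, group, age, interaction),
#'   `pInteraction` (two-sided), `fit` (the `lm` object).
#' @export
interactionRegression <- function(value, age, group) {
    group <- as.factor(group)
    if (nlevels(group) != 2L) stop("group must have exactly two levels")
    if (any(tapply(age, group, function(a) length(a) < 2 || sd(a) == 0)))
        stop("need >= 2 subjects and age variance within each group")
    g <- as.numeric(group) - 1
    fit <- stats::lm(value ~ g * age)
    if (any(is.na(stats::coef(fit))))
        stop("collinear design")
    sm <- summary(fit)$coefficients
    list(coefficients = c(intercept = sm[1, 1], group = sm[2, 1],
                          age = sm[3, 1], interaction = sm[4, 1]),
         pInteraction = sm[4, 4],
         fit = fit)
}

#' Group comparison of every measure in a table
#'
#' Runs [unpairedT()] of DS vs HC (or the table's two group levels) for each
#' named column and adjusts the family of p-values with [bhFdr()].
#'
#' @param tab data.frame with a `group` column.
#' @param cols measure columns to compare.
#' @param q FDR level.
#' @return data.frame: `measure`, `t`, `df`, `p`, `pAdjusted`, `rejected`.
#' @export
groupCompareTable <- function(tab, cols, q = 0.05) {
    gl <- unique(tab$group)
    if (length(gl) != 2L) stop("need exactly two groups")
    res <- lapply(cols, function(cl) {
        r <- unpairedT(tab[[cl]][tab$group == gl[1]],
                       tab[[cl]][tab$group == gl[2]])
        data.frame(measure = cl, t = r$statistic, df = r$df, p = r$p)
    })
    out <- do.call(rbind, res)
    fdr <- bhFdr(out$p, q)
    out$pAdjusted <- fdr$adjusted
    out$rejected <- fdr$rejected
    rownames(out) <- NULL
    out
}
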