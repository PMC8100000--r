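# Independent oracles used to cross-check package implementations.

# Connected components by iterative minimum-label propagation (flood fill
# to a fixed point), independent of the graph-based implementation.
# Returns labels renumbered 1..K by smallest linear member index, the same
# deterministic numbering the package uses.
floodFillOracle <- function(mask, connectivity = 26L) {
    dims <- dim(mask)
    offs <- hippoconn:::connOffsets(connectivity)
    lab <- array(0, dims)
    lab[mask] <- which(mask)  # seed with linear indices
    L <- array(seq_len(prod(dims)), dims)
    repeat {
        old <- lab
        for (i in seq_len(nrow(offs))) {
            dx <- offs[i, 1]; dy <- offs[i, 2]; dz <- offs[i, 3]
            xs <- seq_len(dims[1]); xs <- xs[xs + dx >= 1 & xs + dx <= dims[1]]
            ys <- seq_len(dims[2]); ys <- ys[ys + dy >= 1 & ys + dy <= dims[2]]
            zs <- seq_len(dims[3]); zs <- zs[zs + dz >= 1 & zs + dz <= dims[3]]
            src <- L[xs, ys, zs]
            dst <- L[xs + dx, ys + dy, zs + dz]
            sel <- mask[src] & mask[dst]
            lab[dst[sel]] <- pmin(lab[dst[sel]], lab[src[sel]])
        }
        if (identical(lab, old)) break
    }
    roots <- sort(unique(lab[lab > 0]))
    out <- array(0L, dims)
    out[lab > 0] <- match(lab[lab > 0], roots)
    out
}

# Brute-force double-loop argmax of row maxima with lowest-index tie-break.
bruteArgmaxRow <- function(corr) {
    best <- -Inf; bestRow <- NA_integer_
    for (i in seq_len(nrow(corr))) {
        rowBest <- -Inf
        for (j in seq_len(ncol(corr))) {
            v <- corr[i, j]
            if (!is.na(v) && v > rowBest) rowBest <- v
        }
        if (is.finite(rowBest) && rowBest > best) {
            best <- rowBest
            bestRow <- i
        }
    }
    bestRow
}

# Literal Benjamini-Hochberg step-up: reject the largest k with
# p_(k) <= k*q/m and everything smaller.
bhStepUpOracle <- function(p, q) {
    m <- length(p)
    o <- order(p)
    ps <- p[o]
    k <- which(ps <= seq_len(m) * q / m)
    rejected <- rep(FALSE, m)
    if (length(k) > 0)
        rejected[o[seq_len(max(k))]] <- TRUE
    rejected
}

# Textbook pooled-variance two-sample t.
pooledTOracle <- function(x, y) {
    n1 <- length(x); n2 <- length(y)
    sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
    tt <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
    list(t = tt, df = df, p = 2 * pt(-abs(tt), df))
}

# Normal-equations OLS for value ~ group + age + age:group.
interactionOracle <- function(value, age, group) {
    g <- as.numeric(as.factor(group)) - 1
    X <- cbind(1, g, age, g * age)
    solve(t(X) %*% X, t(X) %*% value)[, 1]
}
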