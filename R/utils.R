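# Internal helpers shared across modules.

checkSameGrid <- function(a, b, what = "inputs") {
    if (!identical(dim(a), dim(b)))
        stop(sprintf("%s are not on the same grid: %s vs %s", what,
                     paste(dim(a), collapse = "x"),
                     paste(dim(b), collapse = "x")))
    invisible(TRUE)
}

# Neighbor offsets for a given 3D connectivity (6, 18 or 26).
connOffsets <- function(connectivity) {
    stopifnot(connectivity %in% c(6L, 18L, 26L))
    g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
    g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
    manh <- rowSums(abs(g))
    keep <- switch(as.character(connectivity),
                   "6"  = manh == 1,
                   "18" = manh <= 2,
                   "26" = rep(TRUE, nrow(g)))
    g[keep, , drop = FALSE]
}

# Label connected components of a logical 3D mask. Components are numbered
# 1..K by their smallest linear (x-fastest) voxel index, so the labeling is
# deterministic. Adjacency is delegated to igraph.
labelComponents <- function(mask, connectivity = 26L) {
    dims <- dim(mask)
    out <- array(0L, dims)
    fg <- which(mask)
    if (length(fg) == 0L)
        return(out)
    compact <- integer(prod(dims))
    compact[fg] <- seq_along(fg)
    L <- array(seq_len(prod(dims)), dims)
    offs <- connOffsets(connectivity)
    offs <- offs[offs[, 3] > 0 |
                 (offs[, 3] == 0 & offs[, 2] > 0) |
                 (offs[, 3] == 0 & offs[, 2] == 0 & offs[, 1] > 0),
                 , drop = FALSE]
    edges <- vector("list", nrow(offs))
    for (i in seq_len(nrow(offs))) {
        dx <- offs[i, 1]; dy <- offs[i, 2]; dz <- offs[i, 3]
        xs <- seq_len(dims[1]); xs <- xs[xs + dx >= 1 & xs + dx <= dims[1]]
        ys <- seq_len(dims[2]); ys <- ys[ys + dy >= 1 & ys + dy <= dims[2]]
        zs <- seq_len(dims[3]); zs <- zs[zs + dz >= 1 & zs + dz <= dims[3]]
        src <- L[xs, ys, zs]
        dst <- L[xs + dx, ys + dy, zs + dz]
        sel <- mask[src] & mask[dst]
        edges[[i]] <- cbind(compact[src[sel]], compact[dst[sel]])
    }
    edges <- do.call(rbind, edges)
    g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
    if (nrow(edges) > 0)
        g <- igraph::add_edges(g, t(edges))
    memb <- igraph::components(g)$membership
    # renumber components by smallest member linear index
    firstIdx <- tapply(fg, memb, min)
    rank <- match(seq_along(firstIdx), order(firstIdx))
    out[fg] <- rank[memb]
    out
}

# Sample standard deviation along rows of a matrix (n-1 denominator).
rowSds <- function(m) {
    n <- ncol(m)
    mu <- rowMeans(m)
    sqrt(rowSums((m - mu)^2) / (n - 1))
}

# Normalized 1D Gaussian kernel sampled at integer offsets, radius 4 sigma.
gaussianKernel1d <- function(sigmaVox) {
    r <- max(1L, ceiling(4 * sigmaVox))
    k <- exp(-((-r:r)^2) / (2 * sigmaVox^2))
    k / sum(k)
}
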