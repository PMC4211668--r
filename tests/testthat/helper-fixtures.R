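# Shared fixtures, all generated in code.

# Tiny cloud from explicit coordinates/types.
makeCloud <- function(x, y, z, types, ...) {
    IsletPointCloud(x = x, y = y, z = z, cellType = types, ...)
}

# Jittered HCP cluster as a cloud (physical diameter 1), plus the
# underlying cluster for ground-truth adjacency.
jitteredHCP <- function(n, jitterSd = 0.05, seed = 42) {
    set.seed(seed)
    cl <- buildCluster("hcp", n)
    xyz <- cl@sites + matrix(rnorm(3 * n, sd = jitterSd), n, 3)
    list(cloud = IsletPointCloud(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                                 cellType = rep("beta", n)),
         cluster = cl)
}

# Exhaustive Boltzmann contact-count means for a small binary graph:
# enumerate all placements of nAlpha alpha cells, weight by exp(-E/eF).
boltzmannMeans <- function(graph, nAlpha, J, eF) {
    n <- nCells(graph)
    e <- contactEdges(graph)
    sel <- utils::combn(n, nAlpha)
    stats <- apply(sel, 2, function(ix) {
        tau <- rep("beta", n)
        tau[ix] <- "alpha"
        naa <- sum(tau[e[, 1]] == "alpha" & tau[e[, 2]] == "alpha")
        nab <- sum(tau[e[, 1]] != tau[e[, 2]])
        nbb <- sum(tau[e[, 1]] == "beta" & tau[e[, 2]] == "beta")
        c(E = selfEnergy(graph, tau, J), naa = naa, nab = nab, nbb = nbb)
    })
    w <- exp(-(stats["E", ] - min(stats["E", ])) / eF)
    w <- w / sum(w)
    c(`alpha-alpha` = sum(w * stats["naa", ]),
      `alpha-beta` = sum(w * stats["nab", ]),
      `beta-beta` = sum(w * stats["nbb", ]))
}

# Random binary assignment factor with fixed counts.
randomTypes <- function(nAlpha, nBeta) {
    factor(sample(rep(c("alpha", "beta"), c(nAlpha, nBeta))),
           levels = c("alpha", "beta"))
}
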