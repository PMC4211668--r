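test_that("self-energy is the negated sum of contact attractions", {
    single <- ContactGraph(2, rbind(c(1, 2)))
    expect_equal(selfEnergy(single, c("beta", "beta"),
                            AttractionSet(Jbb = 1, Jab = 0.9)), -1)

    tri <- ContactGraph(3, rbind(c(1, 2), c(2, 3), c(1, 3)))
    expect_equal(selfEnergy(tri, c("alpha", "beta", "beta"),
                            AttractionSet(Jbb = 1, Jab = 0.9)), -2.8)

    empty <- ContactGraph(3, matrix(integer(0), ncol = 2))
    expect_equal(selfEnergy(empty, rep("beta", 3),
                            AttractionSet(Jbb = 1, Jab = 0.9)), 0)

    # missing attraction entry for a present pair
    expect_error(selfEnergy(tri, c("alpha", "beta", "delta"),
                            AttractionSet(Jbb = 1, Jab = 0.9)),
                 "delta")
})

test_that("local swap energy equals full re-summation", {
    fix <- jitteredHCP(80, seed = 3)
    g <- buildContactGraph(fix$cloud)
    csr <- isletmc:::.graphCSR(g)
    J <- AttractionSet(Jbb = 1.2, Jab = 0.8, Jaa = 1)
    Jm <- attractionMatrix(J)[c("alpha", "beta"), c("alpha", "beta")]
    set.seed(4)
    tau <- randomTypes(20, 60)
    for (k in 1:25) {
        ab <- sample(80, 2)
        tau2 <- tau
        tau2[ab] <- tau[rev(ab)]
        dLocal <- isletmc:::.swap_delta_energy(
            csr$adj, csr$off, as.integer(tau) - 1L, Jm,
            ab[1] - 1L, ab[2] - 1L)
        dFull <- selfEnergy(g, tau2, J) - selfEnergy(g, tau, J)
        expect_equal(dLocal, dFull, tolerance = 1e-12)
    }
    # same-type swap never changes the energy
    ix <- which(tau == "beta")[1:2]
    expect_equal(isletmc:::.swap_delta_energy(
        csr$adj, csr$off, as.integer(tau) - 1L, Jm,
        ix[1] - 1L, ix[2] - 1L), 0)
})

test_that("equal attractions reproduce the exact random-permutation
           contact expectation", {
    cl <- buildCluster("hcp", 200)
    nA <- 40; nB <- 160
    set.seed(10)
    # independent replicate chains give a clean SE for the MC mean
    chains <- replicate(16, {
        res <- metropolisEquilibrate(cl@graph, randomTypes(nA, nB),
                                     AttractionSet(Jbb = 1, Jab = 1,
                                                   Jaa = 1),
                                     MCConfig(eF = 0.6, nEquil = 200,
                                              nRecord = 500))
        res$summary@pairMean["alpha-beta"]
    })
    nEdges <- nrow(contactEdges(cl))
    exact <- nEdges * 2 * nA * nB / (200 * 199)
    expect_lt(abs(mean(chains) - exact), 3 * sd(chains) / sqrt(16))
})

test_that("Monte Carlo means match exhaustive Boltzmann enumeration on a
           12-site fragment", {
    cl <- buildCluster("hcp", 12)
    J <- AttractionSet(Jbb = 1.2, Jab = 0.85, Jaa = 1)
    exact <- boltzmannMeans(cl@graph, nAlpha = 6, J = J, eF = 0.6)
    set.seed(11)
    chains <- replicate(16, {
        res <- metropolisEquilibrate(cl@graph, randomTypes(6, 6), J,
                                     MCConfig(eF = 0.6, nEquil = 1000,
                                              nRecord = 5000))
        res$summary@pairMean
    })
    se <- apply(chains, 1, sd) / sqrt(ncol(chains))
    expect_true(all(abs(rowMeans(chains) - exact) <= 3 * se))
})

test_that("the chain satisfies detailed balance: stationary distribution
           matches Boltzmann weights", {
    # 6-site fragment, 3 alpha / 3 beta: 20 distinguishable assignments
    cl <- buildCluster("hcp", 6)
    g <- cl@graph
    J <- AttractionSet(Jbb = 1.3, Jab = 0.7, Jaa = 1)
    eF <- 0.8
    sel <- utils::combn(6, 3)
    keys <- apply(sel, 2, paste, collapse = "-")
    E <- apply(sel, 2, function(ix) {
        tau <- rep("beta", 6); tau[ix] <- "alpha"
        selfEnergy(g, tau, J)
    })
    pB <- exp(-E / eF); pB <- pB / sum(pB)
    set.seed(12)
    res <- metropolisEquilibrate(g, randomTypes(3, 3), J,
                                 MCConfig(eF = eF, nEquil = 500,
                                          nRecord = 60000),
                                 recordTypes = TRUE)
    thin <- res$typesTrace[seq(1, nrow(res$typesTrace), by = 20), ]
    obsKeys <- apply(thin, 1, function(r) paste(which(r == 0),
                                                collapse = "-"))
    obs <- table(factor(obsKeys, levels = keys))
    gof <- suppressWarnings(stats::chisq.test(obs, p = pB))
    expect_gt(gof$p.value, 0.01)
})

test_that("contact totals and type counts are conserved along the chain", {
    cl <- buildCluster("hcp", 150)
    set.seed(13)
    init <- randomTypes(30, 120)
    res <- metropolisEquilibrate(cl@graph, init,
                                 AttractionSet(Jbb = 1, Jab = 0.9),
                                 MCConfig(eF = 0.6, nEquil = 50,
                                          nRecord = 200),
                                 recordCounts = TRUE)
    nEdges <- nrow(contactEdges(cl))
    expect_true(all(rowSums(res$countsTrace) == nEdges))
    expect_equal(sum(res$summary@pairMean), nEdges)
    expect_equal(as.vector(table(res$assignment)),
                 as.vector(table(init)))
})

test_that("equilibrium heterotypic contacts increase with the
           heterotypic attraction", {
    cl <- buildCluster("hcp", 1357)
    grid <- c(0.7, 0.8, 0.9, 1.0, 1.1)
    set.seed(14)
    chains <- sapply(grid, function(r) replicate(4, {
        res <- metropolisEquilibrate(cl@graph, randomTypes(136, 1221),
                                     AttractionSet(Jbb = 1, Jab = r),
                                     MCConfig(eF = 0.6, nEquil = 800,
                                              nRecord = 200))
        res$summary@pairMean["alpha-beta"]
    }))
    mab <- colMeans(chains)
    seab <- apply(chains, 2, sd) / sqrt(nrow(chains))
    # nondecreasing within combined MC error bars
    for (i in seq_len(length(grid) - 1))
        expect_gt(mab[i + 1] - mab[i],
                  -3 * sqrt(seab[i]^2 + seab[i + 1]^2))
})

test_that("mixing index separates random, sorted and over-mixed
           arrangements", {
    fix <- jitteredHCP(150, seed = 15)
    g <- buildContactGraph(fix$cloud)
    counts <- c(alpha = 30, beta = 120)
    comp <- c(alpha = 0.2, beta = 0.8)
    set.seed(16)
    nsh <- 1000
    mi <- replicate(nsh, {
        tau <- sample(rep(c("alpha", "beta"), counts))
        mixingIndex(contactCounts(g, tau), comp, typeCounts = counts)
    })
    expect_lt(abs(mean(mi) - 1), 3 * sd(mi) / sqrt(nsh))

    # two blocks with a single interface contact
    blocks <- ContactGraph(6, rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5),
                                    c(5, 6)))
    tauB <- c("alpha", "alpha", "alpha", "beta", "beta", "beta")
    miB <- mixingIndex(contactCounts(blocks, tauB),
                       c(alpha = 0.5, beta = 0.5))
    expect_lt(miB, 0.5)

    # alternating types on a 4-cycle: more heterotypic than random
    cyc <- ContactGraph(4, rbind(c(1, 2), c(2, 3), c(3, 4), c(1, 4)))
    miC <- mixingIndex(contactCounts(cyc, c("alpha", "beta", "alpha",
                                            "beta")),
                       c(alpha = 0.5, beta = 0.5),
                       typeCounts = c(alpha = 2, beta = 2))
    expect_gt(miC, 1)

    expect_error(mixingIndex(contactCounts(cyc, rep("beta", 4)),
                             c(alpha = 0, beta = 1)), "undefined")
})
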