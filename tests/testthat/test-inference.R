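test_that("mismatch scores follow the variance-weighted definition", {
    s <- list(pairMean = c(`alpha-alpha` = 5, `alpha-beta` = 20,
                           `beta-beta` = 80),
              pairVar = c(`alpha-alpha` = 4, `alpha-beta` = 1,
                          `beta-beta` = 5))
    obs <- c(`alpha-alpha` = 5, `alpha-beta` = 20, `beta-beta` = 80)
    expect_equal(as.numeric(contactMismatch(obs, s, varFloor = 0)), 0)

    # one pair off by one SD contributes 1/2
    obs1 <- obs; obs1["alpha-alpha"] <- 7
    expect_equal(as.numeric(contactMismatch(obs1, s, varFloor = 0)), 0.5)

    # deviations (2, -1, 0) with variances (4, 1, 5) -> 0.5 + 0.5 + 0
    obs2 <- c(`alpha-alpha` = 7, `alpha-beta` = 19, `beta-beta` = 80)
    X <- contactMismatch(obs2, s, varFloor = 0)
    expect_equal(as.numeric(X), 1.0)
    expect_equal(unname(attr(X, "contributions")), c(0.5, 0.5, 0))

    # the 1/var convention doubles every contribution
    expect_equal(as.numeric(contactMismatch(obs2, s, norm = "one",
                                            varFloor = 0)), 2.0)

    # zero variance: exact match contributes 0, any deviation is infinite
    s0 <- list(pairMean = c(`alpha-beta` = 10), pairVar = c(`alpha-beta` = 0))
    expect_equal(as.numeric(contactMismatch(c(`alpha-beta` = 10), s0,
                                            varFloor = 0)), 0)
    expect_true(is.infinite(contactMismatch(c(`alpha-beta` = 11), s0,
                                            varFloor = 0)))

    # inconsistent pair sets are a consistency error
    expect_error(contactMismatch(c(`alpha-beta` = 1), s), "different")
})

test_that("likelihood weights are stable softmax of -X", {
    expect_equal(likelihoodWeights(c(0, log(2))), c(2 / 3, 1 / 3))
    expect_equal(likelihoodWeights(rep(7, 5)), rep(0.2, 5))
    # a score 50+ below the rest takes essentially all weight
    w <- likelihoodWeights(c(1000, 1060, 940))
    expect_gt(w[3], 1 - 1e-12)
    expect_equal(sum(likelihoodWeights(runif(20, 0, 5))), 1)
    expect_error(likelihoodWeights(rep(Inf, 3)), "degenerate")
})

test_that("delta-ignored censuses drop every delta-touching contact", {
    # alpha - delta - beta chain: both contacts touch delta
    chain <- makeCloud(c(0, 1, 2), rep(0, 3), rep(0, 3),
                       c("alpha", "delta", "beta"))
    expect_equal(sum(deltaIgnoredCensus(chain)), 0L)

    # alpha-beta contact plus a far-away delta
    iso <- makeCloud(c(0, 1, 30), rep(0, 3), rep(0, 3),
                     c("alpha", "beta", "delta"))
    cnt <- deltaIgnoredCensus(iso)
    expect_equal(unname(cnt["alpha-beta"]), 1L)

    # ternary fixture: censored counts equal full census minus
    # delta-touching pairs
    fix <- jitteredHCP(150, seed = 31)
    set.seed(32)
    tau <- sample(rep(c("alpha", "beta", "delta"), c(40, 80, 30)))
    cloud <- makeCloud(cellCoordinates(fix$cloud)[, 1],
                       cellCoordinates(fix$cloud)[, 2],
                       cellCoordinates(fix$cloud)[, 3], tau)
    g <- buildContactGraph(cloud)
    full <- contactCounts(g, cloud)
    cen <- deltaIgnoredCensus(cloud, graph = g)
    expect_equal(cen[c("alpha-alpha", "alpha-beta", "beta-beta")],
                 full[c("alpha-alpha", "alpha-beta", "beta-beta")])
    expect_equal(sum(full) - sum(cen),
                 sum(full[c("alpha-delta", "beta-delta", "delta-delta")]))

    # no delta cells: warning, census equals the binary one
    expect_warning(deltaIgnoredCensus(makeCloud(c(0, 1), c(0, 0), c(0, 0),
                                                c("alpha", "beta"))),
                   "no delta")
})

test_that("posterior pins the reference, normalizes weights, and flags
           low effective sample size", {
    syn <- generateIslet(300, c(alpha = 0.15, beta = 0.85),
                         AttractionSet(Jbb = 1, Jab = 0.9), seed = 41,
                         jitterSd = 0)
    g <- syn$cluster@graph
    obs <- contactCounts(g, as.character(syn$assignment))
    set.seed(42)
    post <- inferAttractions(g, obs, compositionOf(syn$cloud),
                             InferenceConfig(nTrials = 300,
                                             essFloor = 1e6))
    expect_equal(unname(post@mean["alpha-alpha"]), 1)
    expect_equal(unname(post@sd["alpha-alpha"]), 0)
    expect_equal(sum(post@trials$weight), 1, tolerance = 1e-9)
    expect_true(post@lowESS)   # absurd floor must raise the flag
    expect_gt(post@ess, 0)
})

test_that("inference recovers a sorted synthetic islet and rejects
           sorting for a shuffled one", {
    syn <- generateIslet(500, c(alpha = 0.12, beta = 0.88),
                         AttractionSet(Jbb = 1, Jab = 0.85), seed = 51)
    g <- buildContactGraph(syn$cloud)
    obs <- contactCounts(g, syn$cloud)
    comp <- compositionOf(syn$cloud)
    set.seed(52)
    post <- inferAttractions(g, obs, comp,
                             InferenceConfig(nTrials = 800))
    expect_lt(abs(post@ratioMean - 0.85), 3 * post@ratioSD)
    expect_gt(post@mean["beta-beta"], post@mean["alpha-beta"])

    # equal-attraction null: types shuffled on the same graph
    set.seed(53)
    tauR <- sample(as.character(cellTypes(syn$cloud)))
    obsR <- contactCounts(g, tauR)
    post0 <- inferAttractions(g, obsR, comp,
                              InferenceConfig(nTrials = 800))
    expect_lt(abs(post0@ratioMean - 1), 2.5 * post0@ratioSD)
})

test_that("focus-zone refinement does not move the posterior relative to
           a longer uniform-only run", {
    syn <- generateIslet(300, c(alpha = 0.15, beta = 0.85),
                         AttractionSet(Jbb = 1, Jab = 0.9), seed = 61,
                         jitterSd = 0)
    g <- syn$cluster@graph
    obs <- contactCounts(g, as.character(syn$assignment))
    comp <- compositionOf(syn$cloud)
    set.seed(62)
    focus <- inferAttractions(g, obs, comp,
                              InferenceConfig(nTrials = 500))
    set.seed(63)
    unif <- inferAttractions(g, obs, comp,
                             InferenceConfig(nTrials = 2000,
                                             focusFraction = 1))
    sdRef <- pmax(focus@sd[-1], unif@sd[-1])
    expect_true(all(abs(focus@mean[-1] - unif@mean[-1]) <= 2 * sdRef))
})

test_that("posterior ratios are insensitive to the mismatch
           normalization convention", {
    syn <- generateIslet(300, c(alpha = 0.15, beta = 0.85),
                         AttractionSet(Jbb = 1, Jab = 0.9), seed = 71,
                         jitterSd = 0)
    g <- syn$cluster@graph
    obs <- contactCounts(g, as.character(syn$assignment))
    comp <- compositionOf(syn$cloud)
    set.seed(72)
    half <- inferAttractions(g, obs, comp,
                             InferenceConfig(nTrials = 600))
    set.seed(72)
    one <- inferAttractions(g, obs, comp,
                            InferenceConfig(nTrials = 600,
                                            mismatchNorm = "one"))
    expect_lt(abs(half@ratioMean - one@ratioMean),
              max(half@ratioSD, one@ratioSD))
})
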