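test_that("distance criterion links only cells within d_c", {
    # three collinear cells at spacing d: middle-end contacts only
    cloud <- makeCloud(c(0, 1, 2), rep(0, 3), rep(0, 3),
                       c("beta", "beta", "alpha"))
    g <- buildContactGraph(cloud, ContactCriteria(dC = 1.4, thetaC = 30,
                                                  d = 1))
    expect_equal(contactEdges(g), cbind(c(1L, 2L), c(2L, 3L)),
                 ignore_attr = TRUE)
    expect_equal(meanCoordination(g), 4 / 3)
})

test_that("angle rule prunes shielded second-nearest neighbors", {
    # O at origin, A at distance 1, B at distance 1.3 with angle AOB = 20
    # degrees < thetaC = 30: B must be pruned from O's neighbors
    th <- 20 * pi / 180
    cloud <- makeCloud(c(0, 1, 1.3 * cos(th)), c(0, 0, 1.3 * sin(th)),
                       rep(0, 3), c("beta", "beta", "beta"))
    g <- buildContactGraph(cloud, ContactCriteria(dC = 1.4, thetaC = 30,
                                                  d = 1))
    # O-A retained; O-B pruned; A-B distance 0.46 < d_c so A-B remains
    expect_true(all(c(paste(1, 2), paste(2, 3)) %in%
                    paste(contactEdges(g)[, 1], contactEdges(g)[, 2])))
    expect_false(paste(1, 3) %in%
                 paste(contactEdges(g)[, 1], contactEdges(g)[, 2]))

    # with a permissive angle threshold the pruned contact comes back
    g2 <- buildContactGraph(cloud, ContactCriteria(dC = 1.4, thetaC = 10,
                                                   d = 1))
    expect_true(paste(1, 3) %in%
                paste(contactEdges(g2)[, 1], contactEdges(g2)[, 2]))
})

test_that("contact graphs are symmetric, self-edge free, and angle pruning
           only removes edges", {
    fix <- jitteredHCP(150, jitterSd = 0.05, seed = 7)
    g <- buildContactGraph(fix$cloud, ContactCriteria(dC = 1.25,
                                                      thetaC = 30))
    e <- contactEdges(g)
    expect_true(all(e[, 1] < e[, 2]))
    expect_equal(anyDuplicated(e), 0L)
    # distance-only graph (thetaC -> 0) is a superset
    g0 <- buildContactGraph(fix$cloud, ContactCriteria(dC = 1.25,
                                                       thetaC = 1e-6))
    key <- function(g) paste(contactEdges(g)[, 1], contactEdges(g)[, 2])
    expect_true(all(key(g) %in% key(g0)))
})

test_that("jittered HCP cluster yields close-packing-like degrees", {
    fix <- jitteredHCP(200, jitterSd = 0.05, seed = 42)
    g <- buildContactGraph(fix$cloud, ContactCriteria(dC = 1.25,
                                                      thetaC = 30))
    deg <- degreeOf(g)
    expect_gte(mean(deg), 8)
    expect_lte(mean(deg), 12)
    expect_lte(max(deg), 12)
})

test_that("coincident cells are a validation error", {
    cloud <- makeCloud(c(0, 0, 1), c(0, 0, 0), c(0, 0, 0),
                       rep("beta", 3))
    expect_error(buildContactGraph(cloud), "coincident")
})

test_that("threshold tuning reaches the target degree window on a
           jittered HCP cloud and fails on a sparse gas", {
    fix <- jitteredHCP(220, jitterSd = 0.06, seed = 11)
    crit <- tuneContactThresholds(fix$cloud)
    ach <- attr(crit, "achieved")
    expect_gte(ach[["mean"]], 8)
    expect_lte(ach[["mean"]], 9)
    expect_lte(ach[["max"]], 12)
    expect_gte(ach[["min"]], 1)

    # perfect HCP: distance-only contacts are the exact 12-neighbor shells
    perfect <- jitteredHCP(200, jitterSd = 0, seed = 1)
    g <- buildContactGraph(perfect$cloud,
                           ContactCriteria(dC = 1.25, thetaC = 30, d = 1))
    expect_identical(contactEdges(g), contactEdges(perfect$cluster))
    expect_equal(max(degreeOf(g)), 12)

    # dilute uniform gas cannot reach a close-packed degree distribution
    set.seed(3)
    gas <- makeCloud(runif(80, 0, 20), runif(80, 0, 20), runif(80, 0, 20),
                     rep("beta", 80))
    expect_error(tuneContactThresholds(gas),
                 class = "isletmc_tuning_failure")
})

test_that("contact censuses partition edges by endpoint types", {
    # triangle alpha-beta-beta
    tri <- ContactGraph(3, rbind(c(1, 2), c(2, 3), c(1, 3)))
    cnt <- contactCounts(tri, c("alpha", "beta", "beta"))
    expect_equal(cnt, c(`alpha-alpha` = 0L, `alpha-beta` = 2L,
                        `beta-beta` = 1L))
    expect_equal(sum(cnt), nrow(contactEdges(tri)))

    # 4-cycle alternating alpha/beta
    cyc <- ContactGraph(4, rbind(c(1, 2), c(2, 3), c(3, 4), c(1, 4)))
    cnt2 <- contactCounts(cyc, c("alpha", "beta", "alpha", "beta"))
    expect_equal(unname(cnt2["alpha-beta"]), 4L)
    expect_equal(sum(cnt2), 4L)

    # edgeless graph
    empty <- ContactGraph(3, matrix(integer(0), ncol = 2))
    expect_equal(sum(contactCounts(empty, rep("beta", 3))), 0L)
    expect_error(contactRatios(contactCounts(empty, rep("beta", 3))),
                 "undefined")

    # ternary counts normalize to six ratios summing to 1
    set.seed(9)
    fix <- jitteredHCP(120, seed = 5)
    tau <- sample(c("alpha", "beta", "delta"), 120, TRUE)
    g <- buildContactGraph(fix$cloud)
    r <- contactRatios(contactCounts(g, tau))
    expect_length(r, 6)
    expect_equal(sum(r), 1, tolerance = 1e-12)
})

test_that("random-aggregate probabilities follow the composition", {
    p <- randomContactProbabilities(c(alpha = 0.1, beta = 0.9))
    expect_equal(p, c(`alpha-alpha` = 0.01, `alpha-beta` = 0.18,
                      `beta-beta` = 0.81))
    expect_equal(sum(p), 1)
    expect_equal(unname(randomContactProbabilities(
        c(alpha = 0, beta = 1))), 1)
    expect_equal(unname(randomContactProbabilities(
        c(alpha = 0.5, beta = 0.5))), c(0.25, 0.5, 0.25))
    # exact finite-N variant sums to 1 and matches hypergeometric logic
    pf <- randomContactProbabilities(NULL, counts = c(alpha = 3, beta = 7))
    expect_equal(sum(pf), 1, tolerance = 1e-12)
    expect_equal(unname(pf["alpha-alpha"]), 3 * 2 / (10 * 9))
})

test_that("shuffled types reproduce random contact probabilities", {
    # oracle: average contact ratios over many label shuffles of a fixed
    # graph match the exact finite-N expectation within 3 SE
    fix <- jitteredHCP(150, seed = 21)
    g <- buildContactGraph(fix$cloud)
    counts <- c(alpha = 30, beta = 120)
    set.seed(77)
    nsh <- 1000
    rats <- t(replicate(nsh, {
        tau <- sample(rep(c("alpha", "beta"), counts))
        contactRatios(contactCounts(g, tau))
    }))
    expected <- randomContactProbabilities(NULL, counts = counts)
    se <- apply(rats, 2, sd) / sqrt(nsh)
    expect_true(all(abs(colMeans(rats) - expected) <= 3 * se + 1e-12))
})

test_that("mean coordination is twice edges over cells", {
    star <- ContactGraph(7, cbind(1, 2:7))
    expect_equal(meanCoordination(star), 12 / 7)
})
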