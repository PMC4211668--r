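## Bayesian inference of relative attractions from a contact census.
##
## For a trial attraction set J the model equilibrium supplies mean and
## variance of each pair contact count; the mismatch
##   X(J) = sum over pairs (N_obs - mean)^2 / (2 var)
## scores the trial, the likelihood is proportional to exp(-X) (maximum
## entropy), and posterior moments of each J are likelihood-weighted
## moments over all trials. Sampling is two-phase: a uniform scan over the
## prior box, then refinement inside the "focus zone" around the
## lowest-mismatch trials.

#' Mismatch between an observed census and a model equilibrium
#'
#' Variance-weighted squared deviation
#' `X = sum (N_obs - mean)^2 / (2 var)` (or `/var` with
#' `norm = "one"`). Variances are floored at `varFloor` first; with a
#' zero floor, a zero-variance pair contributes 0 on an exact match and
#' `Inf` otherwise.
#'
#' @param observed named contact counts (from [contactCounts()]).
#' @param summary an [EquilibriumSummary-class] (or a list with named
#'   `pairMean` / `pairVar`) over the same pairs.
#' @param norm `"half"` (default) or `"one"`.
#' @param varFloor variance floor, default 1.
#' @return nonnegative scalar with attribute `"contributions"` (per pair).
#' @examples
#' s <- list(pairMean = c(`alpha-beta` = 10), pairVar = c(`alpha-beta` = 4))
#' contactMismatch(c(`alpha-beta` = 12), s, varFloor = 0)   # 4/(2*4) = 0.5
#' @export
contactMismatch <- function(observed, summary, norm = c("half", "one"),
                            varFloor = 1) {
    norm <- match.arg(norm)
    m <- if (is(summary, "EquilibriumSummary")) summary@pairMean
         else summary$pairMean
    v <- if (is(summary, "EquilibriumSummary")) summary@pairVar
         else summary$pairVar
    if (!setequal(names(observed), names(m)))
        stop("observed census and equilibrium summary cover different ",
             "type pairs")
    m <- m[names(observed)]
    v <- pmax(v[names(observed)], varFloor)
    dev2 <- (as.numeric(observed) - m)^2
    contrib <- ifelse(v > 0, dev2 / (if (norm == "half") 2 else 1) / v,
                      ifelse(dev2 == 0, 0, Inf))
    X <- sum(contrib)
    attr(X, "contributions") <- setNames(contrib, names(observed))
    X
}

#' Normalized likelihood weights from mismatch scores
#'
#' `w_k` proportional to `exp(-X_k)`, computed stably by shifting by the
#' minimum score before exponentiation.
#'
#' @param X numeric vector of mismatch scores.
#' @return numeric weights summing to 1.
#' @examples
#' likelihoodWeights(c(0, log(2)))   # c(2/3, 1/3)
#' @export
likelihoodWeights <- function(X) {
    if (!length(X)) stop("no mismatch scores supplied")
    if (all(!is.finite(X)))
        stop("all mismatch scores are infinite; likelihood is degenerate")
    w <- exp(-(X - min(X[is.finite(X)])))
    w[!is.finite(X)] <- 0
    w / sum(w)
}

## Free-pair labels per inference mode (reference alpha-alpha pinned at 1).
.freePairs <- function(mode) {
    switch(mode,
           binary = c("beta-beta", "alpha-beta"),
           deltaIgnored = c("beta-beta", "alpha-beta"),
           ternary = c("beta-beta", "alpha-beta", "delta-delta",
                       "alpha-delta", "beta-delta"))
}

## Full J matrix over `levels` from a named vector of free values; the
## reference pair is pinned at 1.
.buildJ <- function(free, levels) {
    K <- length(levels)
    J <- matrix(0, K, K, dimnames = list(levels, levels))
    J["alpha", "alpha"] <- 1
    for (p in names(free)) {
        xy <- strsplit(p, "-", fixed = TRUE)[[1]]
        J[xy[1], xy[2]] <- J[xy[2], xy[1]] <- free[[p]]
    }
    J
}

#' Infer relative cellular attractions from an observed contact census
#'
#' Two-phase likelihood-reweighted scan over attraction sets. Each trial
#' samples the free J entries, equilibrates the islet's own contact graph
#' at those attractions (fresh random initial assignment with the observed
#' type counts), and scores the mismatch between the model's equilibrium
#' contact counts and the observed census. After the uniform phase the
#' remaining trials are drawn from the focus zone: a box centered on the
#' best trial so far, sized by the spread of the lowest-mismatch trials,
#' expanded by a margin and clipped to the prior range, recomputed over
#' `focusRounds` successive rounds (with escalating inner
#' equilibration). Posterior means
#' and SDs are likelihood-weighted moments over all trials, with each
#' weight `exp(-X)` divided by the trial's known sampling density
#' (importance correction for the box mixture, so the refinement does not
#' distort the posterior); the reference attraction (alpha-alpha) is
#' pinned at 1 with SD 0.
#'
#' Modes: `"binary"` infers `J_bb` and `J_ab` on alpha/beta islets;
#' `"ternary"` infers the 5 free entries on alpha/beta/delta islets;
#' `"deltaIgnored"` infers the binary entries from a structure in which
#' the delta cells are treated as empty sites: their positions stay as
#' frozen holes (they shield contacts, which the contact graph already
#' encodes) and the alpha/beta cells exchange only among the remaining
#' sites, i.e. binary inference on the subgraph induced by the non-delta
#' cells. The observed census must exclude delta-touching contacts (see
#' [deltaIgnoredCensus()]).
#'
#' @param graph the islet's [ContactGraph-class] (over all cells,
#'   including delta, in `deltaIgnored` mode).
#' @param observed named contact counts over the pairs scored in the
#'   chosen mode.
#' @param comp islet composition.
#' @param cfg an [InferenceConfig-class].
#' @param mode inference mode; `"auto"` picks ternary when the composition
#'   has a delta fraction, else binary.
#' @param types cell types of the graph's vertices, required in
#'   `deltaIgnored` mode to locate the delta sites.
#' @return A [PosteriorSummary-class]. A low effective sample size of the
#'   weights raises the `lowESS` flag rather than failing.
#' @seealso [contactMismatch()], [likelihoodWeights()], [generateIslet()]
#' @export
inferAttractions <- function(graph, observed, comp,
                             cfg = InferenceConfig(),
                             mode = c("auto", "binary", "ternary",
                                      "deltaIgnored"),
                             types = NULL) {
    stopifnot(is(graph, "ContactGraph"), is(cfg, "InferenceConfig"))
    validObject(cfg)
    mode <- match.arg(mode)
    if (mode == "auto")
        mode <- if (!is.na(comp["delta"]) && comp["delta"] > 0) "ternary"
                else "binary"
    if (mode == "deltaIgnored") {
        if (is.null(types))
            stop("deltaIgnored mode needs the cell types of the graph's ",
                 "vertices to locate the delta sites")
        types <- as.character(types)
        if (length(types) != nCells(graph))
            stop("types must cover every cell of the graph")
        graph <- .inducedSubgraph(graph, types != "delta")
        ab <- table(factor(types[types != "delta"],
                           levels = c("alpha", "beta")))
        comp <- c(as.numeric(ab) / sum(ab), 0)
        names(comp) <- .CELL_TYPES
    }
    levels <- if (mode == "ternary") .CELL_TYPES else c("alpha", "beta")
    scored <- if (mode == "ternary") .pairNames(.CELL_TYPES)
              else .pairNames(c("alpha", "beta"))
    if (!setequal(names(observed), scored))
        stop("observed census must cover exactly the pairs ",
             paste(scored, collapse = ", "), " in ", mode, " mode")
    counts <- .compToCounts(comp[levels], nCells(graph))
    if (anyNA(counts[levels]) || any(counts[levels] == 0L))
        stop("every active type must have a positive fraction in ", mode,
             " mode")
    if (sum(counts) != nCells(graph))
        stop("composition incompatible with the graph's cell count")
    free <- .freePairs(mode)
    nF <- length(free)
    nTot <- cfg@nTrials
    nUnif <- ceiling(cfg@focusFraction * nTot)
    ## phase schedule: uniform scan, then focusRounds successive
    ## refinements of the focus zone
    nRounds <- min(cfg@focusRounds, max(1L, nTot - nUnif))
    roundSize <- if (nTot > nUnif)
        diff(floor(seq(nUnif, nTot, length.out = nRounds + 1L)))
    else integer(0)
    roundStart <- nUnif + c(0L, cumsum(roundSize))[seq_len(nRounds)] + 1L
    lo <- rep(cfg@range[1], nF)
    hi <- rep(cfg@range[2], nF)
    Js <- matrix(NA_real_, nTot, nF, dimnames = list(NULL, free))
    X <- numeric(nTot)
    phase <- rep("uniform", nTot)
    focusBoxes <- list()
    csr <- .graphCSR(graph)
    fullNames <- .pairNames(levels)
    scoredIdx <- match(scored, fullNames)
    obs <- as.numeric(observed[scored])
    levAll <- rep.int(seq_along(levels), counts[levels])

    ## The number of top trials whose bounding box defines each focus
    ## zone; fixed (not a fraction of all trials) so the zone tightens
    ## as rounds concentrate samples near the mismatch minimum, and never
    ## below ~5 points per free dimension so the box stays full-rank.
    nTop <- max(10L, 5L * nF, ceiling(cfg@focusQuantile * nUnif))
    budget <- 1
    for (k in seq_len(nTot)) {
        if (k %in% roundStart) {
            done <- k - 1L
            ord <- order(X[seq_len(done)])
            best <- ord[seq_len(min(nTop, done))]
            ## zone centered on the single best trial with the top-k
            ## spread as width: recentering lets the zone translate
            ## along a mismatch valley across rounds instead of only
            ## shrinking inside the previous box
            ctr <- Js[ord[1], ]
            wd <- pmax(apply(Js[best, , drop = FALSE], 2, max) -
                       apply(Js[best, , drop = FALSE], 2, min),
                       0.02 * diff(cfg@range))
            half <- (0.5 + cfg@focusExpand) * wd
            lo <- pmax(cfg@range[1], ctr - half)
            hi <- pmin(cfg@range[2], ctr + half)
            box <- rbind(lower = lo, upper = hi)
            colnames(box) <- free
            focusBoxes[[length(focusBoxes) + 1L]] <- box
            phase[k:nTot] <- paste0("focus", length(focusBoxes))
            ## later rounds probe a smaller zone with smaller mismatch
            ## differences, so they get a longer inner equilibration
            budget <- min(4, 2^(length(focusBoxes) - 1))
        }
        Jfree <- lo + (hi - lo) * stats::runif(nF)
        Js[k, ] <- Jfree
        Jm <- .buildJ(setNames(as.list(Jfree), free), levels)
        tau0 <- sample(levAll) - 1L
        res <- .mc_swap_engine(csr$adj, csr$off, as.integer(tau0), Jm,
                               cfg@mc@eF, budget * cfg@mc@nEquil,
                               budget * cfg@mc@nRecord, FALSE, FALSE)
        m <- res$mean[scoredIdx]
        v <- pmax(res$var[scoredIdx], cfg@varFloor)
        dev2 <- (obs - m)^2
        X[k] <- sum(dev2 / (if (cfg@mismatchNorm == "half") 2 else 1) / v)
    }

    ## Importance-corrected likelihood weights: the sampler is a mixture
    ## of uniform boxes (full prior range + the focus boxes), so each
    ## trial's weight is exp(-X) divided by its sampling density. Without
    ## this correction the focus refinement would concentrate posterior
    ## mass wherever the boxes concentrate samples.
    boxes <- c(list(rbind(lower = rep(cfg@range[1], nF),
                          upper = rep(cfg@range[2], nF))), focusBoxes)
    phaseLevels <- c("uniform", paste0("focus", seq_along(focusBoxes)))
    phaseN <- as.numeric(table(factor(phase, levels = phaseLevels)))
    dens <- numeric(nTot)
    for (p in seq_along(boxes)) {
        b <- boxes[[p]]
        inBox <- colSums(t(Js) >= b["lower", ] - 1e-12 &
                         t(Js) <= b["upper", ] + 1e-12) == nF
        dens[inBox] <- dens[inBox] + (phaseN[p] / nTot) /
            prod(b["upper", ] - b["lower", ])
    }
    w <- likelihoodWeights(X) / dens
    w <- w / sum(w)
    postMean <- colSums(w * Js)
    postVar <- colSums(w * (Js - rep(postMean, each = nTot))^2)
    ratio <- Js[, "alpha-beta"] / Js[, "beta-beta"]
    ratioMean <- sum(w * ratio)
    ratioSD <- sqrt(sum(w * (ratio - ratioMean)^2))
    ess <- 1 / sum(w^2)
    trials <- data.frame(Js, X = X, weight = w, phase = phase,
                         check.names = FALSE)
    new("PosteriorSummary",
        mean = c(`alpha-alpha` = 1, postMean),
        sd = c(`alpha-alpha` = 0, sqrt(postVar)),
        ratioMean = ratioMean, ratioSD = ratioSD,
        nTrials = as.integer(nTot), ess = ess,
        lowESS = ess < cfg@essFloor, mode = mode, trials = trials,
        diagnostics = list(focusBoxes = focusBoxes,
                           focusFraction = 1 - nUnif / nTot,
                           eF = cfg@mc@eF))
}

## Subgraph induced by the kept vertices, reindexed 1..sum(keep).
.inducedSubgraph <- function(graph, keep) {
    idx <- integer(graph@nCells)
    idx[keep] <- seq_len(sum(keep))
    e <- graph@edges
    e <- e[keep[e[, 1]] & keep[e[, 2]], , drop = FALSE]
    ContactGraph(sum(keep), cbind(idx[e[, 1]], idx[e[, 2]]))
}

#' Contact census ignoring delta cells as empty sites
#'
#' Builds the contact graph on all cells (delta cells still occupy space
#' and shield other contacts) but excludes every delta-touching contact
#' from the census, so only alpha-alpha, alpha-beta and beta-beta
#' contacts are counted.
#'
#' @param cloud an [IsletPointCloud-class] containing delta cells (a
#'   warning is issued when none are present).
#' @param criteria a [ContactCriteria-class].
#' @param graph optional pre-built [ContactGraph-class] of the full cloud
#'   (avoids rebuilding).
#' @return named integer counts over the alpha/beta pairs.
#' @export
deltaIgnoredCensus <- function(cloud, criteria = ContactCriteria(),
                               graph = NULL) {
    stopifnot(is(cloud, "IsletPointCloud"))
    if (!any(cloud@cellType == "delta"))
        warning("cloud contains no delta cells; census equals the ",
                "full binary census")
    if (is.null(graph)) graph <- buildContactGraph(cloud, criteria)
    ct <- as.character(cloud@cellType)
    e <- graph@edges
    keep <- ct[e[, 1]] != "delta" & ct[e[, 2]] != "delta"
    ab <- c("alpha", "beta")
    pairs <- paste0(pmin(ct[e[keep, 1]], ct[e[keep, 2]]), "-",
                    pmax(ct[e[keep, 1]], ct[e[keep, 2]]))
    cnt <- table(factor(pairs, levels = .pairNames(ab)))
    setNames(as.integer(cnt), .pairNames(ab))
}
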