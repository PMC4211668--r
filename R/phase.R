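## Sorting/mixing phase analysis of binary mixtures on lattice clusters.
##
## Along increasing heterotypic-to-homotypic attraction ratio a finite
## binary mixture passes through four structures: complete sorting (one
## compact minority domain), shell-core sorting (minority enriched on the
## free surface around a majority core), partial mixing (heterotypic
## contacts depleted relative to random but no segregated domain), and
## complete mixing (random-like or heterotypic-favored). Contact-number
## fluctuations peak at the transitions, which is how boundaries are
## located.

#' Sweep equilibrium contact-count fluctuations along an attraction-ratio
#' grid
#'
#' For each ratio `J_het / J_hom` (homotypic attractions fixed at the
#' reference value 1) the cluster is equilibrated at composition
#' `pBeta` and the per-pair means and variances of the contact counts are
#' recorded.
#'
#' @param cluster a [LatticeCluster-class].
#' @param pBeta beta-cell fraction in (0, 1).
#' @param ratioGrid increasing positive heterotypic ratios.
#' @param cfg an [MCConfig-class].
#' @return list with `ratio`, matrices `mean` and `var` (rows = grid
#'   points, columns = type pairs), and `pBeta`.
#' @seealso [detectPhaseBoundaries()], [buildPhaseDiagram()]
#' @export
sweepFluctuations <- function(cluster, pBeta, ratioGrid,
                              cfg = MCConfig(nEquil = 300, nRecord = 300)) {
    stopifnot(is(cluster, "LatticeCluster"))
    if (any(ratioGrid <= 0)) stop("attraction ratios must be positive")
    if (pBeta <= 0 || pBeta >= 1) stop("pBeta must lie in (0, 1)")
    counts <- .compToCounts(c(alpha = 1 - pBeta, beta = pBeta),
                            nCells(cluster))
    pn <- .pairNames(c("alpha", "beta"))
    mm <- vv <- matrix(NA_real_, length(ratioGrid), length(pn),
                       dimnames = list(NULL, pn))
    for (i in seq_along(ratioGrid)) {
        J <- AttractionSet(Jbb = 1, Jab = ratioGrid[i], Jaa = 1)
        res <- metropolisEquilibrate(cluster@graph,
                                     .randomAssignment(counts), J, cfg)
        mm[i, ] <- res$summary@pairMean[pn]
        vv[i, ] <- res$summary@pairVar[pn]
    }
    list(ratio = ratioGrid, mean = mm, var = vv, pBeta = pBeta)
}

## Simple peak finder: interior local maxima of a 3-point moving average,
## kept when their prominence (height above the higher of the two
## flanking minima reachable without crossing a higher point) exceeds
## `minProminence` times the curve range.
.findPeaks <- function(y, minProminence = 0.2) {
    n <- length(y)
    if (n < 5L) stop("need at least 5 grid points to detect peaks")
    s <- as.numeric(stats::filter(y, rep(1 / 3, 3), sides = 2))
    s[1] <- mean(y[1:2]); s[n] <- mean(y[(n - 1):n])
    rng <- diff(range(s))
    if (rng == 0) return(integer(0))
    peaks <- integer(0)
    for (i in 2:(n - 1)) {
        if (s[i] >= s[i - 1] && s[i] > s[i + 1]) {
            leftMin <- min(s[1:i]); rightMin <- min(s[i:n])
            prom <- s[i] - max(leftMin, rightMin)
            if (prom >= minProminence * rng) peaks <- c(peaks, i)
        }
    }
    peaks
}

#' Detect phase boundaries from fluctuation curves
#'
#' Boundaries are the interior local maxima of the smoothed per-pair
#' variance curves (3-point moving average, prominence at least
#' `minProminence` of the curve range); peak locations from the different
#' pair curves are pooled and merged when closer than one grid step.
#'
#' @param curves result of [sweepFluctuations()], or a list with `ratio`
#'   and a `var` matrix.
#' @param minProminence relative prominence threshold.
#' @return increasing numeric vector of boundary ratios (possibly empty:
#'   a single-phase window).
#' @export
detectPhaseBoundaries <- function(curves, minProminence = 0.2) {
    ratio <- curves$ratio
    v <- curves$var
    if (is.null(dim(v))) v <- matrix(v, ncol = 1)
    idx <- sort(unique(unlist(
        lapply(seq_len(ncol(v)), function(j)
            .findPeaks(v[, j], minProminence)))))
    if (!length(idx)) return(numeric(0))
    b <- ratio[idx]
    step <- if (length(ratio) > 1) min(diff(ratio)) else Inf
    merged <- b[1]
    for (x in b[-1]) if (x - merged[length(merged)] > step * 1.5)
        merged <- c(merged, x)
    merged
}

#' Classify a binary structure into a sorting/mixing phase
#'
#' Uses three structural metrics of the assignment on the cluster:
#' the mixing index `m` (heterotypic contacts relative to the exact
#' random expectation), the surface enrichment `se` of the minority type
#' (fraction of minority cells on surface sites divided by the fraction
#' of all sites on the surface; surface = degree below the lattice
#' interior coordination), and the connected-component structure of the
#' minority type. Decision rule, applied in order:
#' \describe{
#'   \item{complete_mixing}{heterotypic contacts not significantly below
#'     the random expectation (within `2 * noise`), or above it.}
#'   \item{complete_sorting}{strong heterotypic depletion
#'     (`m <= sortCut`) with the minority dominated by one domain
#'     (largest component holding at least half the minority cells).}
#'   \item{shell_core_sorting}{minority surface enrichment
#'     `se >= seCut`.}
#'   \item{partial_mixing}{everything else.}
#' }
#' The noise scale is the shuffle SD of the heterotypic contact count
#' when a single snapshot is classified, or the standard error of the
#' recorded mean when an [EquilibriumSummary-class] is supplied. With a
#' `typesTrace` (per-sweep snapshots from [metropolisEquilibrate()]) the
#' surface enrichment is averaged over the recorded sweeps, which makes
#' it far less noisy than a single snapshot.
#'
#' @param cluster a [LatticeCluster-class].
#' @param tau binary factor/character assignment over the sites.
#' @param summary optional [EquilibriumSummary-class] from the run that
#'   produced `tau`; sharpens the mixing-index estimate.
#' @param typesTrace optional integer matrix of recorded assignments
#'   (rows = sweeps), as returned by `metropolisEquilibrate(...,
#'   recordTypes = TRUE)`; 0-based codes in the level order of the run.
#' @param seCut,sortCut decision thresholds.
#' @param nShuffle shuffles used for the snapshot noise scale.
#' @return character phase label, one of `complete_sorting`,
#'   `shell_core_sorting`, `partial_mixing`, `complete_mixing`, with the
#'   metrics attached as attribute `"metrics"`.
#' @export
classifyStructure <- function(cluster, tau, summary = NULL,
                              typesTrace = NULL, seCut = 1.1,
                              sortCut = 0.5, nShuffle = 200) {
    stopifnot(is(cluster, "LatticeCluster"))
    tau <- as.character(tau)
    types <- sort(unique(tau))
    if (length(types) != 2L)
        stop("phase classification needs exactly two cell types present")
    n <- nCells(cluster)
    cnt <- table(factor(tau, levels = types))
    minority <- names(cnt)[which.min(cnt)]
    e <- cluster@graph@edges
    nEdges <- nrow(e)
    nHet <- sum(tau[e[, 1]] != tau[e[, 2]])
    na <- as.integer(cnt[1]); nb <- as.integer(cnt[2])
    expHet <- nEdges * 2 * na * nb / (n * (n - 1))
    if (!is.null(summary)) {
        stopifnot(is(summary, "EquilibriumSummary"))
        hp <- paste0(types[1], "-", types[2])
        obsHet <- unname(summary@pairMean[hp])
        noise <- sqrt(unname(summary@pairVar[hp]) / summary@nSamples)
    } else {
        sh <- replicate(nShuffle, {
            ts <- sample(tau)
            sum(ts[e[, 1]] != ts[e[, 2]])
        })
        noise <- sd(sh)
        obsHet <- nHet
    }
    m <- obsHet / expHet
    interior <- if (cluster@kind == "cubic") 6L else 12L
    surf <- degreeOf(cluster) < interior
    minorityCode <- match(minority, types) - 1L
    seMinority <- if (!is.null(typesTrace)) {
        ## average minority surface occupancy over recorded sweeps
        fSurf <- rowSums(typesTrace[, surf, drop = FALSE] ==
                         minorityCode) / na
        mean(fSurf) / mean(surf)
    } else mean(surf[tau == minority]) / mean(surf)
    minIdx <- which(tau == minority)
    sub <- e[tau[e[, 1]] == minority & tau[e[, 2]] == minority, ,
             drop = FALSE]
    g <- igraph::graph_from_data_frame(
        data.frame(from = match(sub[, 1], minIdx),
                   to = match(sub[, 2], minIdx)),
        directed = FALSE,
        vertices = data.frame(name = seq_along(minIdx)))
    comp <- igraph::components(g)
    largestShare <- max(comp$csize) / length(minIdx)

    label <- if (obsHet >= expHet - 2 * noise) "complete_mixing"
        else if (m <= sortCut && largestShare >= 0.5) "complete_sorting"
        else if (seMinority >= seCut) "shell_core_sorting"
        else "partial_mixing"
    attr(label, "metrics") <- c(mixingIndex = unname(m),
                                surfaceEnrichment = unname(seMinority),
                                componentsPerMinority =
                                    comp$no / length(minIdx),
                                largestComponentShare = largestShare,
                                noise = unname(noise))
    label
}

#' Build a sorting/mixing phase diagram on a lattice cluster
#'
#' Equilibrates every grid point `(pBeta, ratio)` (homotypic attractions
#' pinned at the reference 1), classifies the resulting structure, and
#' detects fluctuation-peak boundaries along each composition row.
#'
#' @param cluster a [LatticeCluster-class].
#' @param pBetaGrid beta fractions in (0, 1).
#' @param ratioGrid increasing heterotypic ratios.
#' @param cfg an [MCConfig-class] applied per grid point.
#' @param ... forwarded to [classifyStructure()].
#' @return A [PhaseDiagram-class]; its `grid` slot has one row per point
#'   with the label and structural metrics, and `boundaries` holds the
#'   per-row boundary ratios (rows shorter than 5 points skip detection).
#' @export
buildPhaseDiagram <- function(cluster, pBetaGrid, ratioGrid,
                              cfg = MCConfig(nEquil = 1500, nRecord = 300),
                              ...) {
    stopifnot(is(cluster, "LatticeCluster"))
    rows <- list()
    boundaries <- vector("list", length(pBetaGrid))
    names(boundaries) <- as.character(pBetaGrid)
    for (ip in seq_along(pBetaGrid)) {
        p <- pBetaGrid[ip]
        counts <- .compToCounts(c(alpha = 1 - p, beta = p),
                                nCells(cluster))
        vmat <- matrix(NA_real_, length(ratioGrid), 3)
        for (ir in seq_along(ratioGrid)) {
            r <- ratioGrid[ir]
            J <- AttractionSet(Jbb = 1, Jab = r, Jaa = 1)
            res <- metropolisEquilibrate(cluster@graph,
                                         .randomAssignment(counts), J, cfg,
                                         recordTypes = TRUE)
            vmat[ir, ] <- res$summary@pairVar
            lab <- classifyStructure(cluster, res$assignment,
                                     summary = res$summary,
                                     typesTrace = res$typesTrace, ...)
            met <- attr(lab, "metrics")
            rows[[length(rows) + 1L]] <- data.frame(
                pBeta = p, ratio = r, label = as.character(lab),
                mixingIndex = met[["mixingIndex"]],
                surfaceEnrichment = met[["surfaceEnrichment"]],
                componentsPerMinority = met[["componentsPerMinority"]])
        }
        if (length(ratioGrid) >= 5L)
            boundaries[[ip]] <- detectPhaseBoundaries(
                list(ratio = ratioGrid, var = vmat))
    }
    grid <- do.call(rbind, rows)
    grid$label <- factor(grid$label, levels = .PHASE_LEVELS)
    new("PhaseDiagram", grid = grid, boundaries = boundaries,
        kind = cluster@kind)
}
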