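## Contact determination from 3D coordinates.
##
## Two-stage criterion: (1) distance - cells closer than dC * d are
## neighbor candidates; (2) angle - scanning candidates nearest-first, a
## farther candidate is discarded when a retained nearer neighbor subtends
## an angle below thetaC at the focal cell (it is geometrically shielded,
## i.e. a second-nearest neighbor). An edge survives only when retained
## from both endpoints, which keeps the graph symmetric.

## Pair labels in the engine's upper-triangular order for a level set.
.pairNames <- function(levels) {
    K <- length(levels)
    out <- character(0)
    for (a in seq_len(K))
        for (b in a:K)
            out <- c(out, paste0(levels[a], "-", levels[b]))
    out
}

## CSR adjacency (0-based) for the C++ kernels.
.graphCSR <- function(graph) {
    n <- graph@nCells
    e <- graph@edges
    if (!nrow(e)) return(list(adj = integer(0), off = integer(n + 1)))
    from <- c(e[, 1], e[, 2])
    to <- c(e[, 2], e[, 1])
    o <- order(from, to)
    list(adj = as.integer(to[o] - 1L),
         off = as.integer(c(0L, cumsum(tabulate(from, nbins = n)))))
}

## Median nearest-neighbor distance: the working estimate of the cell
## diameter d ("mean distance between nearest nuclei").
.estimateDiameter <- function(D) {
    diag(D) <- Inf
    median(apply(D, 1, min))
}

#' Build the cell-cell contact graph of an islet
#'
#' Applies the combined distance and angle criterion to the 3D nuclear
#' coordinates of a cloud. Candidates within `dC * d` of a cell are
#' scanned nearest-first (distance ties broken by cell id); a farther
#' candidate is pruned when an already retained nearer neighbor subtends
#' an angle below `thetaC` at the focal cell. An edge is kept only when
#' both endpoints retain each other.
#'
#' @param cloud an [IsletPointCloud-class].
#' @param criteria a [ContactCriteria-class]; when its `d` is `NA` the
#'   nominal cell diameter is estimated as the median nearest-neighbor
#'   distance of the cloud.
#' @return A [ContactGraph-class].
#' @examples
#' cloud <- IsletPointCloud(x = c(0, 1, 2), y = rep(0, 3), z = rep(0, 3),
#'                          cellType = c("beta", "beta", "alpha"))
#' g <- buildContactGraph(cloud, ContactCriteria(dC = 1.4, thetaC = 30,
#'                                               d = 1))
#' contactEdges(g)    # middle cell contacts both ends; no end-end contact
#' @export
buildContactGraph <- function(cloud, criteria = ContactCriteria()) {
    stopifnot(is(cloud, "IsletPointCloud"), is(criteria, "ContactCriteria"))
    validObject(criteria)
    coords <- cloud@coords
    D <- as.matrix(dist(coords))
    off <- D[upper.tri(D)]
    if (any(off == 0))
        stop("coincident cell coordinates (zero distance between distinct ",
             "cells); upstream segmentation problem")
    d <- if (is.na(criteria@d)) .estimateDiameter(D) else criteria@d
    retained <- .retainedNeighbors(coords, D, cloud@cellId,
                                   criteria@dC * d, criteria@thetaC)
    .edgesFromRetained(retained, nrow(coords))
}

## Per-cell retained neighbor sets under the distance + angle rule.
.retainedNeighbors <- function(coords, D, cellId, dcAbs, thetaC) {
    n <- nrow(coords)
    cosThr <- cos(thetaC * pi / 180)
    diag(D) <- Inf
    retained <- vector("list", n)
    for (i in seq_len(n)) {
        cand <- which(D[i, ] <= dcAbs)
        if (!length(cand)) next
        cand <- cand[order(D[i, cand], cellId[cand])]
        keep <- integer(0)
        for (j in cand) {
            shielded <- FALSE
            for (a in keep) {
                num <- sum((coords[a, ] - coords[i, ]) *
                           (coords[j, ] - coords[i, ]))
                if (num / (D[i, a] * D[i, j]) > cosThr) {
                    shielded <- TRUE
                    break
                }
            }
            if (!shielded) keep <- c(keep, j)
        }
        retained[[i]] <- keep
    }
    retained
}

.edgesFromRetained <- function(retained, n) {
    from <- rep.int(seq_len(n), lengths(retained))
    to <- unlist(retained, use.names = FALSE)
    if (!length(to)) return(ContactGraph(n, matrix(integer(0), ncol = 2)))
    ## symmetric retention: keep i-j only if both directions present
    key <- paste(pmin(from, to), pmax(from, to))
    keep <- key %in% names(which(table(key) == 2L))
    e <- unique(cbind(pmin(from, to), pmax(from, to))[keep, , drop = FALSE])
    ContactGraph(n, e)
}

#' Tune contact thresholds against a target degree distribution
#'
#' Grid search over `(dC, thetaC)` for the combination whose contact graph
#' has a mean degree inside the target window (8 to 9 contacting neighbors
#' on average) while respecting at most `maxDegree` (12, the close-packing
#' bound) and at least `minDegree` (1) contacts per cell. The `dC` grid
#' stays below the cubic second-neighbor distance `sqrt(2) * d` that upper-
#' bounds a meaningful threshold.
#'
#' @param cloud an [IsletPointCloud-class] with at least 50 cells.
#' @param targetMean length-2 window for the mean degree.
#' @param minDegree,maxDegree admissible extreme degrees.
#' @param dCGrid,thetaCGrid search grids.
#' @return A [ContactCriteria-class] with the estimated diameter filled in
#'   and an attribute `"achieved"` holding the mean/min/max degree.
#'   Throws a condition of class `isletmc_tuning_failure` (with the best
#'   candidate attached as its `best` field) when no grid point satisfies
#'   the constraints.
#' @export
tuneContactThresholds <- function(cloud, targetMean = c(8, 9),
                                  minDegree = 1, maxDegree = 12,
                                  dCGrid = seq(1.05, 1.40, by = 0.05),
                                  thetaCGrid = seq(15, 45, by = 5)) {
    stopifnot(is(cloud, "IsletPointCloud"))
    if (nCells(cloud) < 50L)
        stop("threshold tuning needs at least 50 cells")
    coords <- cloud@coords
    D <- as.matrix(dist(coords))
    if (any(D[upper.tri(D)] == 0))
        stop("coincident cell coordinates")
    d <- .estimateDiameter(D)
    grid <- expand.grid(dC = dCGrid, thetaC = thetaCGrid)
    stats <- lapply(seq_len(nrow(grid)), function(k) {
        retained <- .retainedNeighbors(coords, D, cloud@cellId,
                                       grid$dC[k] * d, grid$thetaC[k])
        deg <- degreeOf(.edgesFromRetained(retained, nrow(coords)))
        c(mean = mean(deg), min = min(deg), max = max(deg))
    })
    stats <- do.call(rbind, stats)
    mid <- mean(targetMean)
    distTo <- pmax(0, stats[, "mean"] - targetMean[2],
                   targetMean[1] - stats[, "mean"])
    feasible <- stats[, "min"] >= minDegree & stats[, "max"] <= maxDegree &
        distTo == 0
    bestIdx <- order(distTo, abs(stats[, "mean"] - mid))[1]
    if (!any(feasible)) {
        best <- c(grid[bestIdx, ], stats[bestIdx, ])
        stop(errorCondition(
            paste0("no (dC, thetaC) grid point reaches the target degree ",
                   "distribution; best mean degree ",
                   sprintf("%.2f", stats[bestIdx, "mean"])),
            best = best, class = "isletmc_tuning_failure"))
    }
    idx <- which(feasible)[order(abs(stats[feasible, "mean"] - mid))][1]
    out <- ContactCriteria(dC = grid$dC[idx], thetaC = grid$thetaC[idx],
                           d = d)
    attr(out, "achieved") <- stats[idx, ]
    out
}

#' Contact census by type pair
#'
#' Classifies every contact of the graph by the types of its endpoints.
#'
#' @param graph a [ContactGraph-class] built from `cloud`.
#' @param cloud the matching [IsletPointCloud-class], or a factor/character
#'   vector of cell types of matching length.
#' @return named integer vector of contact counts per unordered type pair
#'   (pairs of absent types are dropped); the counts partition the edges.
#' @examples
#' cloud <- IsletPointCloud(x = c(0, 1, 2), y = c(0, 1, 0), z = rep(0, 3),
#'                          cellType = c("alpha", "beta", "beta"))
#' g <- ContactGraph(3, rbind(c(1, 2), c(2, 3), c(1, 3)))
#' contactCounts(g, cloud)   # alpha-beta 2, beta-beta 1
#' @export
contactCounts <- function(graph, cloud) {
    stopifnot(is(graph, "ContactGraph"))
    ct <- if (is(cloud, "IsletPointCloud")) cloud@cellType
          else factor(as.character(cloud), levels = .CELL_TYPES)
    if (length(ct) != graph@nCells)
        stop("graph and cloud disagree on the number of cells")
    present <- levels(ct)[tabulate(ct, 3L) > 0L]
    ct2 <- factor(as.character(ct), levels = present)
    csr <- .graphCSR(graph)
    cnt <- .pair_contact_counts(csr$adj, csr$off,
                                as.integer(ct2) - 1L, length(present))
    setNames(as.integer(cnt), .pairNames(present))
}

#' Contact ratios
#'
#' Normalizes a contact census to fractions of the total contact number.
#'
#' @param counts named contact counts as from [contactCounts()].
#' @return named numeric vector summing to 1.
#' @export
contactRatios <- function(counts) {
    total <- sum(counts)
    if (total < 1) stop("contact ratios are undefined for an empty census")
    counts / total
}

#' Random-aggregate contact probabilities
#'
#' The theoretical contact ratios of a random cell arrangement: p_x^2 for
#' homotypic and 2 p_x p_y for heterotypic pairs. With integer type counts
#' supplied, the exact finite-N permutation expectation
#' n_x (n_x - 1) / (N (N - 1)) resp. 2 n_x n_y / (N (N - 1)) is returned
#' instead.
#'
#' @param comp composition as from [compositionOf()]; entries of absent
#'   types may be 0 and are dropped.
#' @param counts optional named integer type counts for the exact
#'   finite-N form.
#' @return named numeric vector over type pairs, summing to 1.
#' @examples
#' randomContactProbabilities(c(alpha = 0.1, beta = 0.9))
#' # alpha-alpha 0.01, alpha-beta 0.18, beta-beta 0.81
#' @export
randomContactProbabilities <- function(comp, counts = NULL) {
    if (!is.null(counts)) {
        counts <- counts[counts > 0]
        N <- sum(counts)
        lev <- names(counts)
        K <- length(lev)
        out <- numeric(0)
        for (a in seq_len(K)) for (b in a:K) {
            p <- if (a == b) counts[a] * (counts[a] - 1) else
                2 * counts[a] * counts[b]
            out <- c(out, p / (N * (N - 1)))
        }
        return(setNames(out, .pairNames(lev)))
    }
    if (abs(sum(comp) - 1) > 1e-8) stop("composition must sum to 1")
    comp <- comp[comp > 0]
    lev <- names(comp)
    K <- length(lev)
    out <- numeric(0)
    for (a in seq_len(K)) for (b in a:K)
        out <- c(out, if (a == b) comp[a]^2 else 2 * comp[a] * comp[b])
    setNames(out, .pairNames(lev))
}
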