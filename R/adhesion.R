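## Differential-adhesion energy and Metropolis type-swap equilibration.
##
## The islet self-energy is E = -sum over contacts of J_{tau(i) tau(j)}:
## stronger attractions make contacts costlier to dissociate, so E <= 0
## and equilibrium structures maximize the summed attraction. Dynamics
## exchange the types of two randomly chosen cells while positions (and
## hence the contact graph) stay fixed, conserving the type counts.

## Integer type counts realizing a composition on N cells
## (largest-remainder rounding; recorded rounding is the caller's job).
.compToCounts <- function(comp, N) {
    comp <- comp[comp > 0]
    raw <- comp * N
    cnt <- floor(raw)
    rem <- N - sum(cnt)
    if (rem > 0) {
        up <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
        cnt[up] <- cnt[up] + 1
    }
    cnt <- cnt[cnt > 0]
    setNames(as.integer(cnt), names(cnt))
}

## Random assignment with fixed counts, as a factor over the count names.
.randomAssignment <- function(counts) {
    lev <- names(counts)
    factor(sample(rep.int(lev, counts)), levels = lev)
}

## J matrix aligned to a level set, from an AttractionSet or raw matrix.
.alignJ <- function(J, levels) {
    Jm <- if (is(J, "AttractionSet")) J@J else J
    if (!all(levels %in% rownames(Jm)))
        stop("attraction set lacks entries for type(s): ",
             paste(setdiff(levels, rownames(Jm)), collapse = ", "))
    Jm[levels, levels, drop = FALSE]
}

#' Islet self-energy
#'
#' `E = -sum over contacts of J_{tau(i) tau(j)}`; the negative sign
#' encodes that external energy is needed to dissociate a contact, so E
#' is never positive.
#'
#' @param graph a [ContactGraph-class].
#' @param tau factor (or character) of cell types covering all vertices.
#' @param J an [AttractionSet-class] (or named symmetric matrix) covering
#'   every type pair present on an edge.
#' @return numeric scalar, `<= 0`.
#' @examples
#' g <- ContactGraph(3, rbind(c(1, 2), c(2, 3), c(1, 3)))
#' selfEnergy(g, c("alpha", "beta", "beta"),
#'            AttractionSet(Jbb = 1, Jab = 0.9))   # -2.8
#' @export
selfEnergy <- function(graph, tau, J) {
    stopifnot(is(graph, "ContactGraph"))
    tau <- as.character(tau)
    if (length(tau) != graph@nCells)
        stop("tau must assign a type to every cell of the graph")
    Jm <- .alignJ(J, sort(unique(tau)))
    e <- graph@edges
    if (!nrow(e)) return(0)
    -sum(Jm[cbind(tau[e[, 1]], tau[e[, 2]])])
}

#' Equilibrate a type assignment by Metropolis swap Monte Carlo
#'
#' Starting from `initial`, repeatedly proposes to exchange the types of
#' two uniformly chosen cells and accepts with probability
#' `min(1, exp(-dE / eF))`, where `dE` is computed locally from the two
#' affected neighborhoods (with the shared-edge correction when the cells
#' are adjacent). Same-type proposals are no-ops counted as steps, so the
#' chain is unbiased. One sweep is N proposals; after `nEquil` sweeps the
#' per-pair contact counts are recorded once per sweep for `nRecord`
#' sweeps. Type counts are conserved exactly.
#'
#' Randomness comes from R's RNG: call `set.seed()` for reproducibility.
#'
#' @param graph fixed [ContactGraph-class] (cell positions are the
#'   measured coordinates; only types move).
#' @param initial factor of starting types (its levels define the type
#'   universe for the run; unused levels are dropped).
#' @param J [AttractionSet-class] or named symmetric matrix covering the
#'   types of `initial`.
#' @param cfg an [MCConfig-class].
#' @param recordTypes,recordCounts also return per-sweep snapshots of the
#'   assignment / the pair counts (diagnostics; memory grows with
#'   `nRecord`).
#' @return list with elements `assignment` (final factor),
#'   `summary` (an [EquilibriumSummary-class]) and, when requested,
#'   `typesTrace` / `countsTrace` matrices with one row per recorded
#'   sweep.
#' @seealso [selfEnergy()], [inferAttractions()]
#' @export
metropolisEquilibrate <- function(graph, initial, J, cfg = MCConfig(),
                                  recordTypes = FALSE,
                                  recordCounts = FALSE) {
    stopifnot(is(graph, "ContactGraph"), is(cfg, "MCConfig"))
    validObject(cfg)
    initial <- droplevels(as.factor(initial))
    if (length(initial) != graph@nCells)
        stop("initial assignment must cover every cell of the graph")
    lev <- levels(initial)
    Jm <- .alignJ(J, lev)
    csr <- .graphCSR(graph)
    res <- .mc_swap_engine(csr$adj, csr$off, as.integer(initial) - 1L,
                           Jm, cfg@eF, cfg@nEquil, cfg@nRecord,
                           recordTypes, recordCounts)
    pn <- .pairNames(lev)
    summ <- new("EquilibriumSummary",
                pairMean = setNames(res$mean, pn),
                pairVar = setNames(res$var, pn),
                nSamples = as.integer(res$nSamples),
                nEdges = as.integer(res$nEdges),
                acceptanceRate = res$acceptanceRate)
    out <- list(assignment = factor(lev[res$finalTypes + 1L], levels = lev),
                summary = summ)
    if (recordTypes) out$typesTrace <- res$typesTrace
    if (recordCounts) {
        colnames(res$countsTrace) <- pn
        out$countsTrace <- res$countsTrace
    }
    out
}

#' Mixing index: heterotypic contacts relative to the random expectation
#'
#' Ratio of the observed alpha-beta contact fraction to its random-
#' aggregate expectation `2 p_alpha p_beta` (exact finite-N form when
#' integer type counts are supplied). A value of 1 indicates random-like
#' mixing, below 1 a sorting tendency, above 1 checkerboard-like
#' over-mixing.
#'
#' @param counts named contact counts (from [contactCounts()]) or an
#'   [EquilibriumSummary-class] whose mean counts are used.
#' @param comp composition with nonzero alpha and beta fractions.
#' @param typeCounts optional named integer counts for the finite-N
#'   expectation.
#' @return numeric scalar.
#' @export
mixingIndex <- function(counts, comp, typeCounts = NULL) {
    if (is(counts, "EquilibriumSummary")) counts <- counts@pairMean
    if (is.na(comp["alpha"]) || is.na(comp["beta"]) ||
        comp["alpha"] == 0 || comp["beta"] == 0)
        stop("mixing index is undefined when alpha or beta is absent")
    r <- counts["alpha-beta"] / sum(counts)
    expected <- if (!is.null(typeCounts)) {
        N <- sum(typeCounts)
        2 * typeCounts["alpha"] * typeCounts["beta"] / (N * (N - 1))
    } else 2 * comp["alpha"] * comp["beta"]
    unname(r / expected)
}
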