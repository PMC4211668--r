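#' @import methods
#' @importFrom stats median quantile sd setNames var
#' @importFrom utils read.table write.table
#' @useDynLib isletmc, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## Canonical cell-type vocabulary. "empty" is an internal pseudo-type used
## when delta cells are treated as unoccupied sites during inference.
.CELL_TYPES <- c("alpha", "beta", "delta")

#' IsletPointCloud: per-cell 3D coordinates and types for one islet
#'
#' Container for the measured (or simulated) structure of a single islet:
#' one record per endocrine cell with its nuclear position and hormonal
#' type (alpha, beta or delta).
#'
#' @slot isletId single identifier string.
#' @slot species free-text species label (may be empty).
#' @slot cellId character vector of unique per-cell identifiers.
#' @slot coords numeric matrix with columns x, y, z (length units, e.g. um).
#' @slot cellType factor with levels alpha, beta, delta.
#'
#' @seealso [readCellTable()], [generateIslet()], [compositionOf()]
#' @export
setClass("IsletPointCloud",
    representation(isletId = "character", species = "character",
                   cellId = "character", coords = "matrix",
                   cellType = "factor"))

setValidity("IsletPointCloud", function(object) {
    n <- nrow(object@coords)
    if (n < 2L) return("an islet must contain at least 2 cells")
    if (ncol(object@coords) != 3L) return("coords must have 3 columns")
    if (!is.numeric(object@coords) || any(!is.finite(object@coords)))
        return("all coordinates must be finite numbers")
    if (length(object@cellId) != n)
        return("cellId length must match number of coordinate rows")
    if (anyDuplicated(object@cellId))
        return("cell ids must be unique within an islet")
    if (length(object@cellType) != n)
        return("cellType length must match number of coordinate rows")
    if (!identical(levels(object@cellType), .CELL_TYPES))
        return("cellType levels must be alpha, beta, delta")
    if (anyNA(object@cellType))
        return("cellType must not contain missing values")
    TRUE
})

#' Construct an IsletPointCloud
#'
#' @param x,y,z numeric coordinate vectors (same length).
#' @param cellType character or factor of types among
#'   `c("alpha", "beta", "delta")`.
#' @param cellId optional identifiers; defaults to `"c1" ... "cN"`.
#' @param isletId,species metadata strings.
#' @return A validated [IsletPointCloud-class] object.
#' @examples
#' cloud <- IsletPointCloud(x = c(0, 1, 2), y = rep(0, 3), z = rep(0, 3),
#'                          cellType = c("beta", "beta", "alpha"))
#' compositionOf(cloud)
#' @export
IsletPointCloud <- function(x, y, z, cellType, cellId = NULL,
                            isletId = "islet1", species = "") {
    if (is.null(cellId)) cellId <- paste0("c", seq_along(x))
    ct <- as.character(cellType)
    bad <- setdiff(unique(ct), .CELL_TYPES)
    if (length(bad))
        stop("unsupported cell type(s): ", paste(bad, collapse = ", "),
             " (expected alpha, beta or delta)")
    coords <- cbind(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z))
    new("IsletPointCloud", isletId = as.character(isletId)[1],
        species = as.character(species)[1], cellId = as.character(cellId),
        coords = coords, cellType = factor(ct, levels = .CELL_TYPES))
}

#' ContactGraph: symmetric cell-cell contact adjacency
#'
#' Undirected graph over the cells of a cloud (or sites of a lattice
#' cluster); an edge means the two cells are judged to be in physical
#' contact.
#'
#' @slot nCells number of vertices.
#' @slot edges two-column integer matrix of vertex index pairs with
#'   `edges[,1] < edges[,2]`; zero rows for an edgeless graph.
#' @seealso [buildContactGraph()], [contactCounts()], [meanCoordination()]
#' @export
setClass("ContactGraph",
    representation(nCells = "integer", edges = "matrix"))

setValidity("ContactGraph", function(object) {
    e <- object@edges
    if (ncol(e) != 2L) return("edges must have two columns")
    if (nrow(e)) {
        if (!is.numeric(e)) return("edges must be numeric indices")
        if (any(e < 1L | e > object@nCells))
            return("edge endpoints must index cells of the graph")
        if (any(e[, 1] >= e[, 2]))
            return("edges must satisfy i < j (no self-edges, canonical order)")
        if (anyDuplicated(e)) return("duplicate edges are not allowed")
    }
    TRUE
})

#' @rdname ContactGraph-class
#' @param nCells vertex count.
#' @param edges two-column matrix of index pairs (any order; canonicalized).
#' @export
ContactGraph <- function(nCells, edges) {
    edges <- matrix(as.integer(edges), ncol = 2)
    if (nrow(edges)) {
        flip <- edges[, 1] > edges[, 2]
        edges[flip, ] <- edges[flip, 2:1]
        edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
    }
    new("ContactGraph", nCells = as.integer(nCells), edges = edges)
}

#' ContactCriteria: thresholds of the distance + angle contact rule
#'
#' Two cells are contact candidates when their distance is below
#' `dC * d`; a candidate is then discarded when a retained nearer
#' neighbor subtends an angle below `thetaC` at the focal cell
#' (a second-nearest-neighbor shielded behind a first-shell cell).
#'
#' @slot dC distance threshold in multiples of the nominal cell diameter.
#' @slot thetaC angle threshold in degrees, in (0, 90).
#' @slot d nominal cell diameter in coordinate units; `NA` means estimate
#'   it from the cloud as the median nearest-neighbor distance.
#' @seealso [buildContactGraph()], [tuneContactThresholds()]
#' @export
setClass("ContactCriteria",
    representation(dC = "numeric", thetaC = "numeric", d = "numeric"))

setValidity("ContactCriteria", function(object) {
    if (object@dC <= 0) return("dC must be positive")
    if (object@thetaC <= 0 || object@thetaC >= 90)
        return("thetaC must lie strictly between 0 and 90 degrees")
    if (!is.na(object@d) && object@d <= 0) return("d must be positive")
    TRUE
})

#' @rdname ContactCriteria-class
#' @param dC,thetaC,d see slot descriptions. Defaults `dC = 1.25`,
#'   `thetaC = 30` stay below the cubic second-neighbor distance
#'   `sqrt(2) * d` and the close-packed nearest-neighbor angle of 60
#'   degrees that bound them from above.
#' @export
ContactCriteria <- function(dC = 1.25, thetaC = 30, d = NA_real_) {
    new("ContactCriteria", dC = as.numeric(dC), thetaC = as.numeric(thetaC),
        d = as.numeric(d))
}

#' LatticeCluster: finite approximately spherical lattice cluster
#'
#' @slot kind `"cubic"` or `"hcp"`.
#' @slot sites numeric matrix of site coordinates in units of the lattice
#'   spacing (nearest-neighbor distance 1).
#' @slot graph nearest-neighbor adjacency as a [ContactGraph-class].
#' @seealso [buildCluster()], [clusterDegreeStats()]
#' @export
setClass("LatticeCluster",
    representation(kind = "character", sites = "matrix",
                   graph = "ContactGraph"))

setValidity("LatticeCluster", function(object) {
    if (!object@kind %in% c("cubic", "hcp"))
        return("kind must be 'cubic' or 'hcp'")
    if (nrow(object@sites) != object@graph@nCells)
        return("site count must match adjacency vertex count")
    TRUE
})

#' AttractionSet: symmetric relative attraction energies between cell types
#'
#' Dimensionless attraction strengths J_xy in units of the reference
#' attraction (alpha-alpha is pinned to 1 in the standard normalization).
#' A larger J_xy means more energy is needed to dissociate an x-y contact.
#'
#' @slot J symmetric positive numeric matrix with dimnames naming the
#'   active cell types.
#' @seealso [selfEnergy()], [metropolisEquilibrate()], [inferAttractions()]
#' @export
setClass("AttractionSet", representation(J = "matrix"))

setValidity("AttractionSet", function(object) {
    J <- object@J
    if (is.null(dimnames(J)) || !identical(rownames(J), colnames(J)))
        return("J must have matching row and column names")
    if (!all(rownames(J) %in% .CELL_TYPES))
        return("J types must be among alpha, beta, delta")
    if (!isTRUE(all.equal(J, t(J)))) return("J must be symmetric")
    if (any(!is.finite(J)) || any(J <= 0))
        return("all attraction energies must be finite and positive")
    TRUE
})

#' @rdname AttractionSet-class
#'
#' @param Jbb,Jab beta-beta and alpha-beta attractions (required).
#' @param Jaa reference alpha-alpha attraction, default 1.
#' @param Jdd,Jad,Jbd delta attractions; supply all three for a ternary
#'   set, or none for a binary alpha/beta set.
#' @examples
#' AttractionSet(Jbb = 0.97, Jab = 0.88)            # binary, mouse-like
#' AttractionSet(Jbb = 0.97, Jab = 0.92, Jdd = 1.03,
#'               Jad = 0.93, Jbd = 0.90)            # ternary
#' @export
AttractionSet <- function(Jbb, Jab, Jaa = 1,
                          Jdd = NULL, Jad = NULL, Jbd = NULL) {
    hasDelta <- !is.null(Jdd) || !is.null(Jad) || !is.null(Jbd)
    if (hasDelta && (is.null(Jdd) || is.null(Jad) || is.null(Jbd)))
        stop("a ternary attraction set needs Jdd, Jad and Jbd together")
    if (hasDelta) {
        J <- matrix(c(Jaa, Jab, Jad,
                      Jab, Jbb, Jbd,
                      Jad, Jbd, Jdd), 3, 3,
                    dimnames = list(.CELL_TYPES, .CELL_TYPES))
    } else {
        J <- matrix(c(Jaa, Jab, Jab, Jbb), 2, 2,
                    dimnames = list(c("alpha", "beta"), c("alpha", "beta")))
    }
    new("AttractionSet", J = J)
}

#' MCConfig: Metropolis Monte Carlo settings
#'
#' @slot eF fluctuation (thermal) energy in units of the reference
#'   attraction; models cell motility. Must be positive and should stay
#'   below the attraction energies so aggregates remain ordered.
#' @slot nEquil equilibration sweeps (one sweep = N proposed swaps).
#' @slot nRecord recording sweeps; contact counts are sampled once per
#'   sweep.
#' @seealso [metropolisEquilibrate()]
#' @export
setClass("MCConfig",
    representation(eF = "numeric", nEquil = "integer", nRecord = "integer"))

setValidity("MCConfig", function(object) {
    if (object@eF <= 0) return("eF must be positive")
    if (object@nEquil < 0L) return("nEquil must be >= 0")
    if (object@nRecord < 1L) return("nRecord must be >= 1")
    TRUE
})

#' @rdname MCConfig-class
#' @param eF,nEquil,nRecord see slots. Defaults (`eF = 0.6`, 2000 + 1000
#'   sweeps) are sized for islets of up to ~3500 cells.
#' @export
MCConfig <- function(eF = 0.6, nEquil = 2000, nRecord = 1000) {
    new("MCConfig", eF = as.numeric(eF), nEquil = as.integer(nEquil),
        nRecord = as.integer(nRecord))
}

#' EquilibriumSummary: Monte Carlo contact-count moments at fixed J
#'
#' @slot pairMean named mean contact count per unordered type pair.
#' @slot pairVar named variance over recorded sweeps.
#' @slot nSamples number of recorded sweeps.
#' @slot nEdges total number of contacts (constant during swaps).
#' @slot acceptanceRate fraction of proposals accepted.
#' @export
setClass("EquilibriumSummary",
    representation(pairMean = "numeric", pairVar = "numeric",
                   nSamples = "integer", nEdges = "integer",
                   acceptanceRate = "numeric"))

setValidity("EquilibriumSummary", function(object) {
    if (!identical(names(object@pairMean), names(object@pairVar)))
        return("pairMean and pairVar must share names")
    if (any(object@pairVar < 0)) return("variances must be nonnegative")
    if (abs(sum(object@pairMean) - object@nEdges) > 1e-6)
        return("mean contact counts must sum to the edge count")
    TRUE
})

#' InferenceConfig: settings of the attraction-inference procedure
#'
#' @slot range lower/upper bound of the uniform prior for each free J.
#' @slot nTrials total number of sampled attraction sets.
#' @slot focusFraction fraction of trials drawn uniformly before switching
#'   to the focus zone.
#' @slot focusQuantile lowest-mismatch quantile defining the focus zone.
#' @slot focusExpand relative margin added to each side of the focus box.
#' @slot focusRounds number of successive focus-zone refinements the
#'   non-uniform trials are split into; each round recomputes the zone
#'   from the best trials so far. More rounds sharpen the sampling for
#'   high-dimensional (ternary) searches.
#' @slot essFloor effective-sample-size threshold below which the result
#'   is flagged.
#' @slot mismatchNorm `"half"` for contributions d^2/(2 var), `"one"` for
#'   d^2/var.
#' @slot varFloor lower bound applied to equilibrium variances before the
#'   mismatch is formed (guards rare pairs with near-zero variance).
#' @slot mc [MCConfig-class] used for the per-trial equilibrations.
#' @seealso [inferAttractions()]
#' @export
setClass("InferenceConfig",
    representation(range = "numeric", nTrials = "integer",
                   focusFraction = "numeric", focusQuantile = "numeric",
                   focusExpand = "numeric", focusRounds = "integer",
                   essFloor = "numeric", mismatchNorm = "character",
                   varFloor = "numeric", mc = "MCConfig"))

setValidity("InferenceConfig", function(object) {
    if (length(object@range) != 2L || object@range[1] <= 0 ||
        diff(object@range) <= 0)
        return("range must be positive and increasing")
    if (object@nTrials < 100L) return("nTrials must be >= 100")
    if (object@focusFraction <= 0 || object@focusFraction > 1)
        return("focusFraction must be in (0, 1]")
    if (object@focusRounds < 1L) return("focusRounds must be >= 1")
    if (!object@mismatchNorm %in% c("half", "one"))
        return("mismatchNorm must be 'half' or 'one'")
    TRUE
})

#' @rdname InferenceConfig-class
#' @param range,nTrials,focusFraction,focusQuantile,focusExpand,
#'   focusRounds,essFloor,mismatchNorm,varFloor,mc see slots.
#' @export
InferenceConfig <- function(range = c(0.5, 1.5), nTrials = 2000,
                            focusFraction = 0.5, focusQuantile = 0.02,
                            focusExpand = 0.25, focusRounds = 3,
                            essFloor = 30,
                            mismatchNorm = c("half", "one"), varFloor = 1,
                            mc = MCConfig(eF = 0.6, nEquil = 120,
                                          nRecord = 60)) {
    new("InferenceConfig", range = as.numeric(range),
        nTrials = as.integer(nTrials),
        focusFraction = as.numeric(focusFraction),
        focusQuantile = as.numeric(focusQuantile),
        focusExpand = as.numeric(focusExpand),
        focusRounds = as.integer(focusRounds),
        essFloor = as.numeric(essFloor),
        mismatchNorm = match.arg(mismatchNorm),
        varFloor = as.numeric(varFloor), mc = mc)
}

#' PosteriorSummary: likelihood-weighted posterior over attraction sets
#'
#' @slot mean,sd named posterior mean and SD per J entry (the pinned
#'   reference has SD 0).
#' @slot ratioMean,ratioSD posterior mean and SD of J_ab / J_bb.
#' @slot nTrials number of trials scored.
#' @slot ess effective sample size of the likelihood weights.
#' @slot lowESS flag raised when `ess` fell below the configured floor.
#' @slot mode `"binary"`, `"ternary"` or `"deltaIgnored"`.
#' @slot trials data.frame of sampled J values, mismatch X, normalized
#'   weight and sampling phase, kept for diagnostics.
#' @slot diagnostics list (focus box, phase fractions, ...).
#' @export
setClass("PosteriorSummary",
    representation(mean = "numeric", sd = "numeric",
                   ratioMean = "numeric", ratioSD = "numeric",
                   nTrials = "integer", ess = "numeric", lowESS = "logical",
                   mode = "character", trials = "data.frame",
                   diagnostics = "list"))

#' PhaseDiagram: labeled sweep over composition and attraction ratio
#'
#' @slot grid data.frame with one row per (pBeta, ratio) grid point:
#'   structural metrics and the assigned phase label.
#' @slot boundaries list (one element per pBeta) of boundary ratios
#'   detected from fluctuation peaks.
#' @slot kind lattice kind the diagram was computed on.
#' @seealso [buildPhaseDiagram()]
#' @export
setClass("PhaseDiagram",
    representation(grid = "data.frame", boundaries = "list",
                   kind = "character"))

## Ordered phase labels, sorting -> mixing
.PHASE_LEVELS <- c("complete_sorting", "shell_core_sorting",
                   "partial_mixing", "complete_mixing")
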