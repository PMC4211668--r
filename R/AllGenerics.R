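#' Number of cells (or lattice sites)
#' @param x an IsletPointCloud, ContactGraph or LatticeCluster.
#' @return integer count.
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' Cell types
#' @param x an IsletPointCloud.
#' @return factor of types with levels alpha, beta, delta.
#' @export
setGeneric("cellTypes", function(x) standardGeneric("cellTypes"))

#' Cell identifiers
#' @param x an IsletPointCloud.
#' @return character vector.
#' @export
setGeneric("cellIds", function(x) standardGeneric("cellIds"))

#' Cell (or site) coordinates
#' @param x an IsletPointCloud or LatticeCluster.
#' @return numeric matrix with columns x, y, z.
#' @export
setGeneric("cellCoordinates", function(x) standardGeneric("cellCoordinates"))

#' Contact edges
#' @param x a ContactGraph or LatticeCluster.
#' @return two-column integer matrix of vertex index pairs (i < j).
#' @export
setGeneric("contactEdges", function(x) standardGeneric("contactEdges"))

#' Per-vertex degree
#' @param x a ContactGraph or LatticeCluster.
#' @return integer vector of contact counts per cell.
#' @export
setGeneric("degreeOf", function(x) standardGeneric("degreeOf"))

#' Mean number of contacting neighbors per cell
#'
#' Defined as `2 * nEdges / nCells`. For the 1357-site reference clusters
#' this coordination number is about 5.4 (cubic) and 10.6 (HCP), the scale
#' against which measured islets are compared.
#'
#' @param x a ContactGraph or LatticeCluster.
#' @return numeric scalar.
#' @examples
#' g <- ContactGraph(7, cbind(1, 2:7))   # star: center + 6 leaves
#' meanCoordination(g)                   # 12/7
#' @export
setGeneric("meanCoordination", function(x) standardGeneric("meanCoordination"))

#' Attraction matrix
#' @param x an AttractionSet.
#' @return symmetric named numeric matrix of J values.
#' @export
setGeneric("attractionMatrix", function(x) standardGeneric("attractionMatrix"))

setMethod("nCells", "IsletPointCloud", function(x) nrow(x@coords))
setMethod("nCells", "ContactGraph", function(x) x@nCells)
setMethod("nCells", "LatticeCluster", function(x) x@graph@nCells)

setMethod("cellTypes", "IsletPointCloud", function(x) x@cellType)
setMethod("cellIds", "IsletPointCloud", function(x) x@cellId)
setMethod("cellCoordinates", "IsletPointCloud", function(x) x@coords)
setMethod("cellCoordinates", "LatticeCluster", function(x) x@sites)

setMethod("contactEdges", "ContactGraph", function(x) x@edges)
setMethod("contactEdges", "LatticeCluster", function(x) x@graph@edges)

setMethod("degreeOf", "ContactGraph", function(x)
    tabulate(x@edges, nbins = x@nCells))
setMethod("degreeOf", "LatticeCluster", function(x) degreeOf(x@graph))

setMethod("meanCoordination", "ContactGraph", function(x)
    2 * nrow(x@edges) / x@nCells)
setMethod("meanCoordination", "LatticeCluster", function(x)
    meanCoordination(x@graph))

setMethod("attractionMatrix", "AttractionSet", function(x) x@J)

setMethod("show", "IsletPointCloud", function(object) {
    comp <- compositionOf(object)
    cat("IsletPointCloud '", object@isletId, "'",
        if (nzchar(object@species)) paste0(" (", object@species, ")"),
        ": ", nCells(object), " cells\n", sep = "")
    cat("  composition: ",
        paste(sprintf("%s %.3f", names(comp), comp), collapse = ", "),
        "\n", sep = "")
})

setMethod("show", "ContactGraph", function(object) {
    cat("ContactGraph: ", object@nCells, " cells, ", nrow(object@edges),
        " contacts (mean coordination ",
        sprintf("%.2f", meanCoordination(object)), ")\n", sep = "")
})

setMethod("show", "LatticeCluster", function(object) {
    cat("LatticeCluster (", object@kind, "): ", nCells(object),
        " sites, mean coordination ",
        sprintf("%.2f", meanCoordination(object)), "\n", sep = "")
})

setMethod("show", "AttractionSet", function(object) {
    cat("AttractionSet (", nrow(object@J), " types):\n", sep = "")
    print(round(object@J, 4))
})

setMethod("show", "EquilibriumSummary", function(object) {
    cat("EquilibriumSummary: ", object@nEdges, " contacts, ",
        object@nSamples, " samples, acceptance ",
        sprintf("%.2f", object@acceptanceRate), "\n", sep = "")
    print(data.frame(mean = round(object@pairMean, 2),
                     var = round(object@pairVar, 2)))
})

setMethod("show", "PosteriorSummary", function(object) {
    cat("PosteriorSummary (", object@mode, " mode, ", object@nTrials,
        " trials, ESS ", sprintf("%.1f", object@ess),
        if (object@lowESS) ", LOW-ESS FLAG", "):\n", sep = "")
    print(data.frame(mean = round(object@mean, 3),
                     sd = round(object@sd, 3)))
    cat("  ratio Jab/Jbb = ", sprintf("%.3f +/- %.3f", object@ratioMean,
        object@ratioSD), "\n", sep = "")
})

setMethod("show", "PhaseDiagram", function(object) {
    cat("PhaseDiagram (", object@kind, "): ", nrow(object@grid),
        " grid points\n", sep = "")
    print(table(object@grid$label))
})
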