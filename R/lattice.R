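## Finite, approximately spherical lattice clusters.
##
## Cubic: integer grid, interior coordination 6. HCP: ABAB stacking of
## triangular layers (layer spacing sqrt(2/3)), interior coordination 12.
## Coordinates are exact in closed form with nearest-neighbor distance 1.
## "Approximately spherical" is realized by picking the n sites nearest a
## reference lattice site at the center of a generously sized generating
## block (ties broken by lexicographic coordinate order).

.generatingBlock <- function(kind, n) {
    ## circumradius estimate from the site density (1 for cubic,
    ## sqrt(2) for close packing), plus margin
    dens <- if (kind == "cubic") 1 else sqrt(2)
    R <- ceiling((3 * n / (4 * pi * dens))^(1 / 3)) + 3L
    if (kind == "cubic") {
        g <- expand.grid(x = -R:R, y = -R:R, z = -R:R)
        return(as.matrix(g))
    }
    h <- sqrt(2 / 3)             # layer spacing
    layers <- -R:R
    rows <- -(2 * R):(2 * R)
    cols <- -(2 * R):(2 * R)
    g <- expand.grid(i = cols, j = rows, k = layers)
    odd <- g$k %% 2 != 0
    x <- g$i + g$j / 2 + ifelse(odd, 0.5, 0)
    y <- g$j * sqrt(3) / 2 + ifelse(odd, sqrt(3) / 6, 0)
    z <- g$k * h
    cbind(x = x, y = y, z = z)
}

#' Build an approximately spherical lattice cluster
#'
#' Constructs a finite cluster of `n` sites of a cubic or hexagonal
#' close-packed (HCP) lattice by selecting the sites nearest the center of
#' a large generating block, then connects all site pairs at unit distance.
#' The free (non-periodic) boundary mirrors an islet surface: the 1357-site
#' reference clusters have mean coordination about 5.4 (cubic) and 10.6
#' (HCP) instead of the interior values 6 and 12.
#'
#' @param kind `"cubic"` or `"hcp"`.
#' @param n number of sites (>= 1).
#' @return A [LatticeCluster-class].
#' @examples
#' cl <- buildCluster("cubic", 7)    # center + 6 face neighbors
#' meanCoordination(cl)              # 12/7
#' @export
buildCluster <- function(kind = c("cubic", "hcp"), n) {
    kind <- match.arg(kind)
    n <- as.integer(n)
    if (n < 1L) stop("n must be >= 1")
    block <- .generatingBlock(kind, n)
    if (nrow(block) < n)
        stop("internal error: generating block smaller than n")
    ## reference point: the block site closest to the block centroid
    ctr <- colMeans(block)
    refIdx <- which.min(colSums((t(block) - ctr)^2))
    ref <- block[refIdx, ]
    d2 <- colSums((t(block) - ref)^2)
    ord <- order(d2, block[, 1], block[, 2], block[, 3])
    sites <- block[ord[seq_len(n)], , drop = FALSE]
    rownames(sites) <- NULL
    adj <- .unitDistanceEdges(sites)
    new("LatticeCluster", kind = kind, sites = sites,
        graph = ContactGraph(n, adj))
}

## All site pairs at distance 1 (tolerance 1e-6), via a spatial hash on
## unit cells so clusters of a few thousand sites stay cheap.
.unitDistanceEdges <- function(sites) {
    n <- nrow(sites)
    if (n == 1L) return(matrix(integer(0), ncol = 2))
    cell <- floor(t(t(sites) - apply(sites, 2, min)) + 1e-9)
    key <- paste(cell[, 1], cell[, 2], cell[, 3])
    buckets <- split(seq_len(n), key)
    lookup <- new.env(hash = TRUE, parent = emptyenv())
    for (k in names(buckets)) assign(k, buckets[[k]], envir = lookup)
    offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    res <- vector("list", n)
    for (i in seq_len(n)) {
        cand <- integer(0)
        for (r in seq_len(nrow(offs))) {
            k <- paste(cell[i, 1] + offs[r, 1], cell[i, 2] + offs[r, 2],
                       cell[i, 3] + offs[r, 3])
            if (!is.null(v <- lookup[[k]])) cand <- c(cand, v)
        }
        cand <- cand[cand > i]
        if (!length(cand)) next
        d2 <- colSums((t(sites[cand, , drop = FALSE]) - sites[i, ])^2)
        hit <- cand[abs(d2 - 1) < 1e-6]
        if (length(hit)) res[[i]] <- cbind(i, hit)
    }
    out <- do.call(rbind, res)
    if (is.null(out)) matrix(integer(0), ncol = 2) else out
}

#' Degree statistics of a lattice cluster
#'
#' @param cluster a [LatticeCluster-class].
#' @return named numeric vector `c(mean=, min=, max=)` of site degrees.
#' @export
clusterDegreeStats <- function(cluster) {
    stopifnot(is(cluster, "LatticeCluster"))
    deg <- degreeOf(cluster)
    c(mean = mean(deg), min = min(deg), max = max(deg))
}

#' Convert a lattice cluster to an IsletPointCloud
#'
#' All sites are typed beta by default; supply `cellType` to override.
#' Coordinates are scaled by `spacing` (the physical nearest-neighbor
#' distance).
#'
#' @param cluster a [LatticeCluster-class].
#' @param cellType types for the sites (recycled if length 1).
#' @param spacing physical lattice spacing (e.g. a 10 um cell diameter).
#' @param isletId identifier for the resulting cloud.
#' @return An [IsletPointCloud-class].
#' @export
clusterToCloud <- function(cluster, cellType = "beta", spacing = 1,
                           isletId = "cluster") {
    stopifnot(is(cluster, "LatticeCluster"))
    s <- cluster@sites * spacing
    n <- nrow(s)
    IsletPointCloud(x = s[, 1], y = s[, 2], z = s[, 3],
                    cellType = rep_len(as.character(cellType), n),
                    isletId = isletId)
}
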