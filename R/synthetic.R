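## Synthetic islet generator: HCP lattice clusters with type arrangements
## drawn from the adhesion-model equilibrium at known ground-truth
## attractions, positional jitter, and optional z-flattening (islets
## settle slightly under gravity). HCP is the generative lattice because
## measured islets have near-close-packed coordination (~10.6 at 1357
## cells), much closer to HCP than to a cubic arrangement.

#' Generate a synthetic islet with known ground truth
#'
#' Builds an HCP cluster of `n` sites, equilibrates the type assignment
#' at the ground-truth attractions by Metropolis swap Monte Carlo, then
#' scales coordinates to a physical cell diameter, applies isotropic
#' Gaussian positional jitter and an optional z-compression. Jitter is
#' applied after type equilibration, so the ground-truth contact
#' structure is the lattice adjacency and noise stresses only the
#' geometry stage.
#'
#' @param n number of cells (>= 50).
#' @param comp named composition (e.g. `c(alpha = 0.1, beta = 0.9)`;
#'   fractions are rounded to integer counts by largest remainder and the
#'   realized counts are recorded in the truth record).
#' @param J ground-truth [AttractionSet-class].
#' @param eF fluctuation energy used for the equilibration.
#' @param jitterSd positional noise SD as a fraction of the cell
#'   diameter, in [0, 0.15].
#' @param flatten z-compression factor in [0.7, 1] (1 = none).
#' @param diameter physical cell diameter (coordinate units, e.g. 10 um).
#' @param nEquil equilibration sweeps for the type arrangement.
#' @param seed RNG seed; the truth record plus seed regenerates the cloud
#'   bit-exactly.
#' @param isletId identifier for the generated cloud.
#' @return list with `cloud` (an [IsletPointCloud-class]), `cluster` (the
#'   underlying [LatticeCluster-class]), `assignment` (the equilibrated
#'   types on the lattice), and `truth` (all generating parameters).
#' @examples
#' \donttest{
#' syn <- generateIslet(400, c(alpha = 0.1, beta = 0.9),
#'                      AttractionSet(Jbb = 1, Jab = 0.91), seed = 1)
#' syn$cloud
#' }
#' @export
generateIslet <- function(n, comp, J, eF = 0.6, jitterSd = 0.05,
                          flatten = 1, diameter = 10, nEquil = 400,
                          seed = NULL, isletId = "synthetic") {
    if (n < 50L) stop("synthetic islets need at least 50 cells")
    if (jitterSd < 0 || jitterSd > 0.15)
        stop("jitterSd must lie in [0, 0.15]")
    if (flatten < 0.7 || flatten > 1)
        stop("flatten must lie in [0.7, 1]")
    if (!is.null(seed)) set.seed(seed)
    cluster <- buildCluster("hcp", n)
    counts <- .compToCounts(comp, n)
    res <- metropolisEquilibrate(
        cluster@graph, .randomAssignment(counts), J,
        MCConfig(eF = eF, nEquil = nEquil, nRecord = 1))
    tau <- res$assignment
    xyz <- cluster@sites * diameter
    if (jitterSd > 0)
        xyz <- xyz + matrix(stats::rnorm(3 * n, sd = jitterSd * diameter),
                            n, 3)
    xyz[, 3] <- xyz[, 3] * flatten
    cloud <- IsletPointCloud(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                             cellType = as.character(tau),
                             isletId = isletId, species = "synthetic")
    truth <- list(n = n, counts = as.list(counts),
                  J = if (is(J, "AttractionSet")) J@J else J,
                  eF = eF, jitterSd = jitterSd, flatten = flatten,
                  diameter = diameter, nEquil = nEquil, seed = seed)
    list(cloud = cloud, cluster = cluster, assignment = tau, truth = truth)
}

#' Generate a random cell aggregate
#'
#' An HCP cluster whose type labels are a uniform random permutation of
#' the requested composition: the null model against which islet order is
#' judged (its contact ratios follow the random-aggregate probabilities).
#'
#' @param n number of cells.
#' @param comp named composition.
#' @param diameter physical cell diameter.
#' @param seed RNG seed.
#' @return list with `cloud`, `cluster` and `assignment` as in
#'   [generateIslet()].
#' @export
generateRandomAggregate <- function(n, comp, diameter = 10, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    cluster <- buildCluster("hcp", n)
    counts <- .compToCounts(comp, n)
    tau <- .randomAssignment(counts)
    xyz <- cluster@sites * diameter
    cloud <- IsletPointCloud(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                             cellType = as.character(tau),
                             isletId = "random-aggregate",
                             species = "synthetic")
    list(cloud = cloud, cluster = cluster, assignment = tau)
}
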