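# isletmc

Quantitative analysis of the three-dimensional architecture of
pancreatic islets of Langerhans under the differential adhesion
hypothesis.

Islets are aggregates of hundreds to thousands of hormone-secreting
cells (insulin-secreting β, glucagon-secreting α, somatostatin-secreting
δ). Their spatial arrangement differs between species — rodent islets
show a β core with non-β cells on the mantle, human islets look
intermixed — and the package asks whether one physical rule explains
both. Given per-cell 3D nuclear coordinates and types, it:

* builds the cell–cell **contact graph** with a combined distance +
  angle criterion (threshold distance `d_c`, shielding angle `θ_c`),
  tuned so cells have 8–9 contacts on average and at most 12;
* models the islet as a lattice gas on that fixed graph with a
  **self-energy** `E = −Σ_contacts J_{τ(i)τ(j)}`, where `J_xy` is the
  relative attraction between cell types x and y (reference
  `J_αα = 1`), and equilibrates type arrangements by **Metropolis swap
  Monte Carlo** at fluctuation energy `E_f` (a cell-motility
  temperature);
* solves the inverse problem: infers posterior means and SDs of the
  `J_xy` from an observed contact census via the mismatch
  `X = Σ_pairs (N_obs − ⟨N⟩)² / (2 Var N)` and likelihood `∝ exp(−X)`,
  sampled with an adaptive (importance-corrected) focus-zone scan;
* sweeps composition and attraction ratio on finite **cubic and
  hexagonal close-packed (HCP) lattice clusters** to map the four
  phases of a binary mixture — complete sorting, shell-core sorting,
  partial mixing, complete mixing — with boundaries located at
  contact-number fluctuation peaks;
* **generates synthetic islets** with known ground-truth attractions,
  so the whole pipeline is testable end-to-end without external data.

The package is written Bioconductor-style: S4 classes
(`IsletPointCloud`, `ContactGraph`, `LatticeCluster`, `AttractionSet`,
`EquilibriumSummary`, `PosteriorSummary`, `PhaseDiagram`) with validity
checks and accessors, and a compiled (Rcpp) swap kernel.

## Worked example

Generate a mouse-like synthetic islet (1357 cells, 90% β, ground-truth
attraction ratio `J_αβ/J_ββ = 0.91`, `E_f = 0.6`), rebuild its contact
graph from the jittered coordinates, and infer the attractions back:

```r
library(isletmc)

syn <- generateIslet(1357, c(alpha = 0.1, beta = 0.9),
                     AttractionSet(Jbb = 1, Jab = 0.91), seed = 1)
g   <- buildContactGraph(syn$cloud)
g
#> ContactGraph: 1357 cells, 6713 contacts (mean coordination 9.89)

contactCounts(g, syn$cloud)
#> alpha-alpha  alpha-beta   beta-beta
#>          89        1117        5507

set.seed(2)
post <- inferAttractions(g, contactCounts(g, syn$cloud),
                         compositionOf(syn$cloud),
                         InferenceConfig(nTrials = 2000))
post
#> PosteriorSummary (binary mode, 2000 trials, ESS 175.0):
#>             mean    sd
#> alpha-alpha 1.000 0.000
#> beta-beta   0.912 0.072
#> alpha-beta  0.841 0.061
#>   ratio Jab/Jbb = 0.923 +/- 0.018
```

The mean coordination (9.9) sits near the HCP reference value (10.6
for a 1357-site cluster) rather than the cubic one (5.4), and the
posterior ratio `J_αβ/J_ββ = 0.923 ± 0.018` recovers the ground truth
0.91: homotypic attraction slightly exceeds heterotypic attraction,
the regime that surface-enriches the minority α cells into a mantle.
Classify the equilibrium arrangement and place mouse-like and
human-like islets on the HCP phase diagram:

```r
cl <- buildCluster("hcp", 1357)
set.seed(3)
pd <- buildPhaseDiagram(cl, pBetaGrid = c(0.6, 0.9),
                        ratioGrid = c(0.91, 0.98))
pd@grid[, c("pBeta", "ratio", "label")]
#>   pBeta ratio              label
#> 1   0.6  0.91     partial_mixing
#> 2   0.6  0.98     partial_mixing
#> 3   0.9  0.91 shell_core_sorting
#> 4   0.9  0.98     partial_mixing
```

A mouse-like islet (β fraction 0.9, ratio 0.91) falls in the
shell-core sorting phase; a human-like one (0.6, 0.98) in partial
mixing — the same small homotypic preference produces both
architectures once the composition differs.

See the vignette (`vignettes/islet-architecture.Rmd`) for the model,
parameter meanings, classifier conventions and limitations. A thin
command-line wrapper over these functions is installed at
`inst/scripts/isletmc-cli.R` (subcommands `lattice`, `simulate`,
`contacts`, `equilibrate`, `infer`).

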