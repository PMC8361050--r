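# grntda

Topological and structural-balance analysis of inferred gene regulatory
networks.

Gene expression measures the micro-state of a cell; the couplings between
genes are not observed directly. `grntda` is for researchers who want to
go from an expression matrix (genes × samples) to a *signed weighted
interaction network* and then ask what the network's higher-order shape —
its connected components, loops and voids across interaction strength —
says about a condition, e.g. how a tumor cohort's wiring differs from a
healthy one.

The package implements three layers, each usable on its own:

1. **Network inference.** The maximum-entropy pairwise model for
   continuous expression levels is the multivariate Gaussian
   P(S) ∝ exp[−½ (S−⟨S⟩)ᵀ C⁻¹ (S−⟨S⟩)], whose couplings are
   J_ij = −C⁻¹_ij. Because direct inversion of an estimated covariance is
   never sparse, the precision matrix is estimated by the graphical
   lasso — an ℓ₁-penalized Gaussian maximum-likelihood estimator,
   implemented here from scratch as block coordinate descent with an
   unpenalized diagonal and full KKT diagnostics
   (`graphicalLasso()`, `interactionsFromPrecision()`; RPKM
   normalization and top-variance gene filtering included).
2. **Structural balance.** Closed signed triangles carry energy
   E_ijk = J_ij J_jk J_ki (balanced iff positive); the census, the energy
   landscape, the triadic Hamiltonian H = −Σ E_ijk and the quartic
   square-count energy H = −s(G) over edge-sharing triangle pairs
   (`enumerateTriads()`, `quarticEnergy()`).
3. **Persistent homology.** The network's weighted clique (flag) complex
   is filtered by absolute coupling weight (weak edges enter first);
   Z₂ boundary-matrix reduction yields persistence pairs, barcodes,
   diagrams, Betti curves β₀/β₁/β₂ and essential classes
   (`buildCliqueFiltration()`, `computePersistence()`, `bettiCurve()`),
   cross-checked by an independent rank-based oracle
   (`bettiNumbersStatic()`).

A synthetic-data layer (`generateSparsePrecision()`, `sampleExpression()`,
`generateCohortPair()`, `generateToyNetwork()`) provides Gaussian cohorts
with known sparse signed precision matrices and toy networks with known
homology, so every stage is testable against ground truth without any
download.

## Worked example

Toy network with known homology — an octahedron (whose clique complex is
a 2-sphere) with two pendant 4-cycles attached:

```r
library(grntda)
net <- generateToyNetwork("fig1c_analog")
net
#> InteractionNetwork: 12 genes, 20 edges, sparsity 0.697
#>   weights: 20 positive, 0 negative, |J| in [1, 1]
pd <- computePersistence(buildCliqueFiltration(net))
essentialFeatures(pd)$counts
#> dim0 dim1 dim2
#>    1    2    1
```

One essential component, two essential loops (the pendant cycles), one
essential void (the sphere): the Betti vector (1, 2, 1).

End-to-end two-cohort comparison on synthetic ground truth. The two
cohorts share the same coupling support and signs; only the coupling
*magnitudes* differ — narrow (0.1–0.2) for the "cancer-like" member,
broad (0.1–0.8) for the "normal-like" one:

```r
pair <- generateCohortPair(seed = 1)       # 50 genes, 2000 samples each
cfg  <- cohortConfig()                     # lambda chosen by held-out likelihood
ra <- runCohort(pair[["cancer-like"]], cfg, verbose = FALSE)
rb <- runCohort(pair[["normal-like"]], cfg, verbose = FALSE)
ra
#> CohortTopologyReport 'cancer-like'
#>   network: 50 genes, 656 edges; lambda = 0.006194004
#>   essential classes (components, loops, voids): 1, 0, 2
#>   beta0 connect at 0.01370397 | beta1 onset at 0.005645473 | beta2 plateau 0.07382247 (max 94)
compareCohorts(ra, rb)
#> ComparisonReport: 'cancer-like' vs 'normal-like'
#>   connectsEarlier: cancer-like
#>   loopOnsetEarlier: cancer-like
#>   moreEssentialLoops: tie
#>   moreEssentialVoids: cancer-like
#>   beta2SaturatesEarlier: cancer-like
#>   beta2SaturatesLower: normal-like
```

Read: the narrow-weight cohort's network becomes path-connected at a
smaller threshold (0.0137), its loops appear earlier, and its void curve
saturates earlier — the topological signature of a cohort whose
interaction weights are compressed toward small values. `runCohort(...,
outDir = "...")` persists every intermediate (edge list, triad census,
persistence pairs, Betti curve, JSON summary, resolved config), and
`renderOutputs()` writes persistence-diagram, barcode, Betti-curve and
weight-histogram figures.

A thin command-line wrapper over the same functions is installed at
`inst/scripts/grntda-cli.R` (subcommands `simulate`, `infer`, `balance`,
`topology`, `run`, `compare`).

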