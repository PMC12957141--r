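# hostNiche

Phylogenetic and functional niche breadth of parasites from their host
assemblages.

## The problem

Host specificity — the number and composition of host species a parasite
exploits — is the inverse of its niche breadth. Counting hosts ignores how
different those hosts are; `hostNiche` measures a parasite's niche breadth
as the *diversity* of its host assemblage on two axes:

* **Phylogenetic niche breadth, D_P** — tree-slicing diversity: the
  ultrametric host phylogeny of height *T* is segmented at its node ages
  into evolutionary periods, the number of lineages ancestral to the host
  assemblage (lineage richness *D_k*) is counted within each period, and

  D_P = Σ_k (t_k − t_{k−1}) · D_k / T.

  D_P is 1 for a single host, S on a star tree, and ≈1 for two congeners in
  a deep tree — it reads as "effective lineages, averaged over time".

* **Functional niche breadth, Q** — Rao's quadratic entropy with equal
  host weights over a Gower dissimilarity matrix of mixed-type host traits:

  Q = (1/S²) Σ_i Σ_j d_ij,   d_ij ∈ [0, 1].

Around these two statistics the package provides the complete analysis
pipeline for multi-region ectoparasite survey data (fleas and gamasid mites
on small mammals are the motivating system): tree preparation (edge-aware
majority-rule consensus, ultrametrization by terminal-branch extension,
seeded polytomy resolution, taxonomy-to-tree conversion for taxa lacking a
phylogeny), the dataset filtering rules (commensal host and ubiquitous
parasite exclusions, minimum-host counts per scale), characteristic
abundance and body-size derivation, within-species repeatability of
regional niche breadth (one-way REML ICC with parametric-bootstrap
intervals and a boundary-corrected likelihood-ratio test), phylogenetic
generalized least squares with Pagel's λ/κ/δ optimized by maximum
likelihood, and a synthetic-data generator with known ground truth for
every estimated quantity.

## Worked example

```r
library(hostNiche)

study <- simulateStudy(simulationConfig(seed = 42))   # synthetic survey bundle
res <- runAll(list(
  hostTree = study$hostTree, parasiteTree = study$parasiteTree,
  hostTraits = study$hostTraits, incidence = study$incidence,
  parasiteTraits = study$parasiteTraits, nBoot = 500, seed = 7))

res$T1_icc
#>   metric nSpecies   ICC     SE  CI2.5 CI97.5        P
#> 1     DP       60 0.124 0.0476 0.0272  0.217 0.000493
#> 2      Q       60 0.113 0.0465 0.0244  0.220 0.001424

res$T3_continental_abundance[, c("predictor", "n", "slope", "slopeP", "lambda", "R2")]
#>   predictor  n slope   slopeP lambda    R2
#> 1        DP 60 0.377 6.34e-13  0.698 0.370
#> 2         Q 60 1.192 4.59e-07  0.622 0.357
```

Reading the output: the repeatability of regional niche breadth is weak
(ICC ≈ 0.12) but clearly non-zero — niche breadth behaves as a species
property with large regional scatter — while at the continental scale the
characteristic abundance increases significantly with both phylogenetic and
functional niche breadth (log-log PGLS slopes 0.38 and 1.19, both
P < 1e-6), with substantial phylogenetic signal in the residuals
(λ ≈ 0.6–0.7). Regional versions of the same regressions are mostly
non-significant, the scale-dependence the pipeline is designed to expose.
`runAll()` also returns (and, given `outDir`, writes as CSV) the body-size
suites, the mean-regional vs continental comparison, the per-parasite
host-pool regressions, a run log, and a machine-readable manifest.

The niche-breadth table itself is available directly:

```r
filt <- applyFilters(study$incidence, filterConfig())
nb <- nicheBreadthTable(filt, study$hostTree, gowerMatrix(study$hostTraits))
head(nb[nb$scale == "continental", ])
#>     parasite       scale  S    DP      Q
#> 350     P001 continental 35 9.549 0.349
#> 351     P002 continental 31 8.691 0.337
```

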