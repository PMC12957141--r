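---
title: "Measuring parasite niche breadth: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring parasite niche breadth: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hostNiche)
```

# The problem

Host specificity is a fundamental property of a parasite species: the number
and composition of host species it can exploit. Its inverse — niche breadth —
can be measured on three axes: the count of hosts (numerical), their spread
over the host phylogeny (phylogenetic), and their spread in host trait space
(functional). `hostNiche` implements the latter two for periodic
haematophagous ectoparasites (fleas, gamasid mites) of small mammals surveyed
across many regions, together with the statistical machinery needed to ask
how niche breadth relates to a parasite's characteristic abundance and body
size, whether it is a repeatable species property, and whether it tracks the
diversity of hosts available regionally.

# The two niche-breadth statistics

## Functional niche breadth: Rao's quadratic diversity Q

For a parasite exploiting hosts $\{1,\dots,S\}$ with pairwise functional
dissimilarities $d_{ij} \in [0,1]$ and equal (presence/absence) weights,

$$Q = \frac{1}{S^2} \sum_{i=1}^{S}\sum_{j=1}^{S} d_{ij},$$

which is 0 for a single host and at most $(S-1)/S$. Dissimilarities come
from the Gower coefficient on mixed-type trait tables (quantitative traits
as range-normalized absolute differences, ordinal traits compared on integer
ranks, categorical and binary traits as 0/1 mismatches, per-trait weights
optional). Conventions fixed here, where the underlying method leaves a
choice open:

* **Missing values** use pairwise deletion with denominator renormalization
  — host trait databases are chronically incomplete, and dropping species
  would bias the host sets themselves.
* **Constant traits** (zero range over the supplied table) are excluded from
  all comparisons, with a warning.
* **Ordinal traits** are compared on ranks scaled by the rank range
  (classic Gower); `gowerMatrix(..., ordinal = "mismatch")` switches to a
  categorical treatment.
* **Binary traits** are symmetric: neither state is privileged, so a
  mismatch always counts 1 (hibernation yes/no has no "presence" state).

A schema typing the 13 ecomorphological host traits used for small mammals
(body mass, relative brain mass, longevity, litter size, generation length,
dispersal distance, log range size; habitat breadth; trophic level, foraging
stratum, activity cycle; hibernation, fossoriality) ships in
`inst/extdata/host_trait_schema.csv`.

## Phylogenetic niche breadth: tree-slicing diversity D_P

The ultrametric host tree of height $T$ is cut at every distinct node age,
yielding evolutionary periods $[t_{k-1}, t_k]$. Within a period the number
of distinct lineages ancestral to the assemblage — lineage richness $D_k$,
evaluated at the period midpoint, where it cannot change — is counted, and

$$D_P = \sum_k \frac{t_k - t_{k-1}}{T}\, D_k .$$

$D_P$ is 1 for one host, S on a star phylogeny, and close to 1 for a pair of
congeners in a deep tree (the worked value for two congeners splitting at
1/10 of the tree depth is exactly 1.1): it measures how long, in tree-depth
units, the assemblage has been more than a few lineages.

Two conventions deserve emphasis:

* **Period weighting.** "Averaging the $D_k$" admits either a
  duration-weighted or an unweighted mean; we weight by period duration, the
  natural reading of the evolutionary-period construction (each slice of
  time counts in proportion to its length), and expose
  `weighting = "equal"` for the alternative.
* **Depth context.** $D_P$ for an assemblage is computed against the host
  pool's tree pruned with `pruneKeepDepth()`, which keeps the distance from
  the original root as a stem. Re-rooting at the assemblage MRCA would erase
  precisely the signal the metric exists for: two congeneric hosts and two
  ordinally distant hosts would both span "the whole tree". With the stem
  retained, lineage counts change only at assemblage-internal join ages, so
  the value is identical whether computed on the pool tree or the full tree
  — a property the test suite asserts.
* **Midpoint counting** sidesteps boundary ties at node ages, and collapsing
  duplicate node ages means zero-length branches (from polytomy resolution)
  never create spurious zero-length periods.

# Tree preparation

The host phylogeny is typically a sample of dated trees: `consensusWithEdges()`
builds the majority-rule (>50%) topology and assigns each retained edge the
mean of its length over the trees containing that clade — a deliberately
simple, documented approximation to edge-aware consensus methods.
`forceUltrametricExtend()` ultrametrizes by extending terminal branches to
the maximal depth (idempotent; internal branches untouched).
`resolvePolytomies()` replaces multifurcations by randomly ordered binary
splits with zero-length branches, so the cophenetic matrix is preserved
exactly — since published randomizations differ, distance preservation is
the contract, and the split order is seeded.

When no molecular phylogeny exists (gamasid mites), `taxonomyToTree()` turns
a species/genus/subfamily/family table into a unit-branch rank tree of
height 4: congeners sit at patristic distance 2, confamilials at 6, members
of different families at 8. Branch lengths absent from a Newick string
default to 1, the same convention used when a tree is assembled from
taxonomic topology.

# Repeatability (ICC)

Whether niche breadth is a species property is asked with the one-way
Gaussian random-intercept model
$y_{ij} = \mu + a_i + e_{ij}$, $a_i \sim N(0,\sigma^2_b)$,
$e_{ij} \sim N(0,\sigma^2_w)$, fitted by REML:
$R = \sigma^2_b / (\sigma^2_b + \sigma^2_w)$. The implementation profiles
$\mu$ and $\sigma^2_w$ out in closed form per group, leaving a 1-D bounded
optimization over the variance ratio — this makes a fit cheap enough that
the parametric bootstrap (1000 refits per interval by default) and the
calibration studies in the test suite run in seconds, and it matches `lme4`
to six decimals on the same data. Design choices:

* **Raw metrics by default** (a `reml`/log switch is left to the caller via
  transformation of the input) — the Gaussian mixed-model default of the
  standard repeatability tools.
* **Unbalanced group sizes** (species occur in different numbers of regions)
  are handled natively by REML; no subsampling.
* **Confidence intervals** are percentile bootstrap intervals; the p-value
  is the likelihood-ratio test of $\sigma^2_b = 0$ against the 50:50
  $\chi^2_0/\chi^2_1$ boundary mixture, the standard correction for a
  variance component on its boundary. Its empirical size at $\alpha = 0.05$
  is asserted to lie in $[0.02, 0.07]$ over 2000 null simulations.

# Phylogenetic regressions

Cross-species regressions use GLS with the Brownian expectation
$V_{ij} = $ shared root-to-MRCA path length, transformed by Pagel's
parameters in the fixed order **kappa → delta → lambda**: branch lengths are
raised to $\kappa$ ($0^0 := 0$) and the covariance rebuilt; $V$ is raised
element-wise to $\delta$ and rescaled to preserve the maximal diagonal; and
off-diagonals are scaled by $\lambda$. Estimation is by Cholesky whitening
(never an explicit inverse); $R^2$ and the model F test are computed in the
whitened space against the GLS intercept-only null.

Transform parameters named in `optimize` are estimated by profile **maximum
likelihood** (coefficient SEs from the same ML fit) with bounded multi-start
optimization: both bounds, the midpoint, and two seeded random starts;
bound-adjacent optima are flagged. The default frees $\lambda$ only, with
$\kappa = \delta = 1$: joint three-parameter ML on a few dozen taxa is
weakly identified, and $\lambda$ carries the phylogenetic-signal correction
that matters for inference. Bounds default to $\lambda \in [0,1]$,
$\kappa, \delta \in [10^{-6}, 3]$.

Reported equations follow the convention that an intercept indistinguishable
from zero ($p \ge 0.05$) is dropped and the through-origin model is quoted
(`maybeDropIntercept()`, both variants retained). This mirrors how such
model tables are usually printed; the threshold is an inference about that
reporting style, not a claim about the data.

The within-species host-pool regressions (each parasite's regional breadth
against the diversity of all hosts recorded in that region) run across
conspecific observations, where a cross-species phylogenetic covariance has
no meaning; they therefore use ordinary least squares, with the same
intercept convention.

# The filtering rules

`applyFilters()` removes (a) commensal ubiquitous rodents (*Rattus rattus*,
*R. norvegicus*, *Mus musculus*) and their characteristic ubiquitous fleas
(*Xenopsylla cheopis*, *Nosopsyllus fasciatus*), then (b) every parasite
recorded on fewer than three host species — applied within each region for
the regional record set and on the pooled records for the continental set,
independently, so a parasite can be continental-only. Regional regression
suites require at least eight parasites in a region; repeatability requires
two regions per species; host-pool regressions require eight. All thresholds
live in `filterConfig()`. Filtering is idempotent, and the derivation of the
characteristic abundance (region-mean abundance per host, then the maximal
host = principal host; ties broken lexicographically and logged) is applied
after it.

# The synthetic-data generator

`simulateStudy()` produces a complete input bundle with known ground truth:

* **Trees**: pure-birth (Yule) trees rescaled to height 1 — simpler than
  birth-death and sufficient for the covariance structures under test; the
  unit height makes $\theta$ and the log-log slopes scale-free.
* **Traits**: Brownian motion for quantitative traits, symmetric Markov
  switching for categorical/binary, a discretized Brownian trait (5 ranks)
  for the ordinal column; 7/1/3/2 columns by default, matching the 13-trait
  host table.
* **Incidence**: each region carries a random 55–90% subset of the host
  pool (regional faunas differ); each parasite has a focal host and draws
  its per-region host set with weights $\propto e^{-\theta \cdot d}$
  (patristic distance to the focal host), so $\theta \ge 0$ tunes
  phylogenetic clustering. With probability $1-f$ the focal host is shifted
  within a region — parasites do switch principal hosts across regions —
  and $f$ also sets the species-persistent share of the log host-set-size
  variance. $f$ is calibrated by a pilot pass (a grid of candidate splits
  under common random numbers, choosing the realized point-ICC of regional
  $D_P$ closest to `targetICC`): the mapping from these dials to the ICC of
  a nonlinear tree statistic has no closed form.
* **Responses**: $\log CA = a + b_{CA} \log D_P^{cont} + \varepsilon$ and
  $\log BS$ likewise, with $\varepsilon$ multivariate normal under the
  $\lambda$-transformed Brownian covariance of the parasite tree. Because
  body size enters the analysis as a predictor of breadth while it is
  generated from breadth, only the **sign** of $b_{BS}$ is recoverable by
  the body-size suite (regression attenuation); the tests assert exactly
  that.

Default conditions: 40 hosts, 60 parasites, 15 regions, regional occupancy
0.4 (so roughly 24 species per region and about a tenth of parasites in
eight or more regions), mean host-set size 6, $\theta = 8$, target ICC 0.12,
$b_{CA} = 0.3$, $b_{BS} = -0.2$, residual $\lambda = 0.5$. These are
desk-scale stand-ins chosen to reproduce the qualitative structure of
multi-region ectoparasite surveys: weak but positive within-species
repeatability, a clear continental abundance–breadth relationship, and
regional relationships that are mostly absent because regional breadth is
dominated by within-species noise.

What the generator deliberately does **not** emulate: realistic
biogeographic structure (regions are exchangeable), correlated host traits,
abundance-dependent detection, or taxonomic error. Passing tests therefore
show that the estimators recover what they claim under the stated model,
not that any particular field dataset satisfies that model.

# Worked example

```{r example, eval = FALSE}
study <- simulateStudy(simulationConfig(seed = 42))
res <- runAll(list(
  hostTree = study$hostTree, parasiteTree = study$parasiteTree,
  hostTraits = study$hostTraits, incidence = study$incidence,
  parasiteTraits = study$parasiteTraits, nBoot = 500, seed = 7,
  outDir = "results"))
res$T1_icc                    # repeatability of DP and Q
res$T3_continental_abundance  # continental abundance ~ breadth PGLS
```

The same pipeline runs from files (Newick trees, CSV tables written by
`writeStudy()` or assembled from real surveys) by passing paths instead of
objects.

# Numerical choices and limitations

* Ultrametricity is checked at a relative tolerance of $10^{-8}$; node ages
  within $10^{-9} T$ of each other are merged when slicing.
* Covariance matrices failing a Cholesky factorization receive one jitter of
  $10^{-10}\,\overline{\mathrm{diag}}$ before erroring.
* Perfect-fit degeneracies (zero residual variance) are treated as flat
  profile likelihoods rather than optimizer failures, and NaN intercept
  p-values count as "unsupported" for the intercept-dropping rule.
* Natural logarithms are used throughout.
* The consensus is a topology-majority/mean-length approximation, not a
  full edge-aware consensus; trees with conflicting near-50% clades will
  lose resolution.
* ICC is computed on the raw metric scale by default; strongly skewed
  metrics may warrant a log transform, applied by the caller.
* All simulation-based checks in the tests and the acceptance script state
  their replicate counts (200 PGLS replicates at 100 taxa, 1000/2000 ICC
  and LRT replicates, one end-to-end bundle at the default sizes); these
  are the problem sizes the package's own guarantees are stated at.
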