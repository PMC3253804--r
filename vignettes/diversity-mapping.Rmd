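---
title: "Mapping SSR diversity with circular-neighborhood re-sampling"
author: "divmapr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping SSR diversity with circular-neighborhood re-sampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divmapr)
```

## The problem

Collections of georeferenced genotypes — landrace fruit trees in home
gardens, wild relatives in natural stands — are sampled unevenly: a
handful of trees per village, villages scattered over thousands of
kilometers. Conservation planning nonetheless needs *maps*: where is
allelic richness highest, where is inbreeding elevated, where does a
clonal commercial cultivar dominate, which areas carry alleles that no
genebank holds, and where has sampling simply not reached. `divmapr`
implements that mapping pipeline for diploid codominant markers
(microsatellites), end to end, with a synthetic-landscape generator that
makes every stage testable against known truth.

## Circular-neighborhood re-sampling

The central device is a deliberate trade between spatial resolution and
per-cell sample size. Statistics are mapped on a fine grid (default cell
size 1/6° = 10 arcminutes, roughly 18 km in the Andes), but each tree is
*re-sampled* into every cell of a circular neighborhood with a one-degree
diameter (~111 km) around it. A cell's sample is thus all trees of the
surrounding landscape, so neighboring cells share trees and the map is a
smoothed, high-resolution surface.

The geometric rule is node-anchored: a tree is snapped to its nearest
grid node (cell corner) and copied into every cell whose center lies
strictly within half the diameter of that node. For the default
parameters this stencil is the 6×6 block of cells around the node minus
its four corners — exactly 32 cells for every tree, so n trees always
produce 32·n (tree, cell) records, and a complete 9-locus diploid table
yields 2·9·32·n re-sampled allele copies. This fixed-stencil convention
is the only center-in-circle rule that gives a constant per-tree cell
count; the alternative of centering the circle on the tree itself is
available (`resample_trees(..., anchor = "tree")`) but yields a
position-dependent 26–32 cells (established here by brute-force
enumeration over tree positions). The grid is extended, never clipped, so
border trees contribute full stencils.

Two numerical conventions matter. Cells are half-open, so a point on a
shared boundary belongs to the east/north cell and every point maps to
exactly one cell. Node snapping uses a half-up tie-break,
`floor(x + 0.5)` on coordinates pre-rounded to 9 decimals: R's default
round-half-even would let trees exactly midway between nodes snap
inconsistently after a rigid shift of the whole dataset, breaking the
property that translating all trees by one cell size translates the count
raster unchanged.

## Per-cell statistics

All statistics are computed from the *re-sampled* trees of a cell (one
tree can contribute to up to 32 cells; no de-duplication — that is the
point of the method). Per locus, the gene count N is twice the number of
non-missing genotypes; statistics average over loci with data.

* **Na** — mean distinct alleles per locus. Reported for every occupied
  cell.
* **Rarefied Na** — expected distinct alleles in a standardized draw of
  `g` genes, `E[A_g] = sum_i (1 - choose(N - N_i, g) / choose(N, g))`,
  computed with log-binomials for stability. The default `g = 40`
  interprets the field convention "rarefy to 20 trees" as 20 diploid
  individuals = 40 genes (the gene-based convention of the standard
  rarefaction software); a flag overrides it. Loci with N < g return NA
  rather than an extrapolation.
* **Locally common alleles** — alleles with within-cell frequency
  strictly above 5% that occur in at most 25% of *occupied* cells. The
  occupancy denominator excludes empty cells because they carry no
  frequency information; the strict `>` on frequency and inclusive `<=`
  on occupancy follow the stated definition of the thresholds.
* **He, Ho** — gene diversity `1 - sum(p^2)` and the observed
  heterozygote fraction. He is the uncorrected plug-in estimator (the
  GenAlEx convention); it is biased low by roughly `1/(2n)` relative, a
  point that matters when interpreting F below.
* **F** — `1 - Ho/He` per locus, averaged over *polymorphic* loci
  (monomorphic loci are uninformative about inbreeding); NA when every
  locus is monomorphic. Negative values flag heterozygote excess, the
  signature of clonally propagated heterozygous cultivars.
* **GD** — squared codominant genotypic distance to a reference
  cultivar, per locus 0/1/2/3/4 for identical, one-step, disjoint-het,
  hom-vs-disjoint-het and opposite-homozygote pairs, summed over shared
  loci and averaged over the cell's trees. The test suite checks it
  against the independent closed form: half the squared Euclidean
  distance between allele-count vectors.

Statistics that are unstable in small samples (rarefied Na, He, Ho, F,
GD) are suppressed below `min_n = 20` re-sampled trees per cell; Na and
the locally-common-allele count are reported for all occupied cells.

## Coordinate cleaning

Before gridding, coordinates are screened against environmental layers
(classically the 19 bioclim variables): a sample is excluded when it is a
reverse-jackknife outlier on at least two layers. The critical gap is
`t = (0.95·sqrt(n) + 0.2)·(range/50)`. The cited method leaves the exact
tail rule underspecified, so the implementation pins it down as follows:
working on the sorted unique values, a tail value (and its duplicates) is
flagged when the gap separating it from the rest both exceeds `t` *and*
strictly dominates every other gap among the remaining values, iterating
outward until neither tail qualifies. The dominance condition is what
"separated from the body" must mean for the screen to be sane: without
it, any evenly spaced small sample (three equidistant values, say) would
flag both extremes, since `t` shrinks with the range. The procedure is
deterministic and invariant under affine rescaling because gaps and
threshold scale together. The administrative check (optional, needs
user-supplied level-1 polygons) flags points farther than a 20-arcminute
buffer from their declared unit, with distances in degree space to match
the buffer's definition.

## Admixture clustering and ΔK

Cluster structure is inferred under the standard admixture model: each
allele copy of individual i at locus l comes from cluster k with
probability `Q[i,k]` and is allele a with probability `P[k,l,a]`. Instead
of Bayesian MCMC, the package maximizes this likelihood by EM — the same
Q/P semantics, but deterministic given a seed and desk-scale. The
per-iteration log-likelihood is non-decreasing (tested); frequencies are
floored at 1e-6 and renormalized so a private allele can never produce a
minus-infinity likelihood; Q rows are initialized from a symmetric
Dirichlet(1) and P from perturbed pooled frequencies. Twenty independent
restarts per K stand in for the usual twenty independent runs, and
Evanno's `ΔK(K) = |L'(K+1) - L'(K)| / sd(L(K))` is computed from the
restart log-likelihoods. This is a documented deviation: the original ΔK
uses the estimated model evidence of MCMC runs, while here the spread
comes from EM local maxima. When all restarts converge to the same
optimum the sd is 0 and ΔK is undefined at that K (excluded from the
argmax with a warning); in practice the contrast between a strong
two-population signal and the flat tail of larger K is what ΔK detects,
and on simulated two-pool landscapes the argmax lands on K = 2 with
membership accuracy above 95%.

## Ex situ gaps and distribution-surface evaluation

The gap analysis is exact bookkeeping: alleles present in at least one in
situ tree and absent from every ex situ accession, plus a per-cell
richness map counting how many such alleles each cell's re-sampled trees
carry. For sampling-coverage evaluation the package accepts any modeled
distribution raster. It also ships a transparent climate-envelope scorer
(fraction of variables inside the presences' percentile envelope) so the
pipeline runs self-contained; this scorer is a simple presence-only model
in its own right, not an emulation of any particular external modeling
tool. The surface is binarized at the 10-percentile training presence
threshold — the smallest observed score with at most 10% of training
presences strictly below it, i.e. `sorted[floor(n·pct/100) + 1]`, which
also handles the all-equal and pct = 0 edge cases. Evaluation uses a
seeded 80/20 presence split plus uniform pseudo-absences (five per test
presence, drawn in the presence bounding box expanded by 10% per side),
rank-based AUC (ties one half, equal to exhaustive pair counting), and
Cohen's kappa at the stated threshold — or, when none is given, maximized
over candidate thresholds with the maximizer reported. Coverage classes
over the modeled-present cells (≥ 20, 1–19, 0 re-sampled trees) always
partition 100%.

## The synthetic landscape

`landscape_config()` describes the generator; defaults emulate the
statistical structure of the Andean study system the pipeline targets:
1,504 trees clustered around 14 sampling hubs over an 18° × 20° extent,
nine loci with 8 (one locus 7) ancestral alleles (71 total), two
ancestral gene pools mixing along a logistic latitudinal cline, a
high-diversity hotspot contributing two extra rare alleles per locus, a
clonal cultivar patch (the reference genotype is heterozygous at 8 of 9
loci, so its clones show Ho = 0.89 and strongly negative F), a regional
inbreeding coefficient of 0.3, one third of trees labeled ex situ, and
the hotspot's extra alleles withheld from the ex situ subset, planting an
exactly known genebank gap.

Genotypes follow the standard inbreeding mixture: with mixture
frequencies `p = q·p_A + (1-q)·p_B`, `P(ii) = p_i² + F·p_i(1-p_i)` and
`P(ij) = 2·p_i·p_j·(1-F)`, implemented by drawing the second allele copy
identical to the first with probability F. This gives `E[1 - Ho/He] = F`
at the population level, which turns fixation-index recovery into a
quantitative check. What the generator does *not* emulate: linkage and
allele-size homoplasy, isolation-by-distance within a gene pool,
genotyping error and allelic dropout, and realistic spatial
autocorrelation of climate. Passing recovery tests therefore demonstrate
that the estimators measure what they claim under the model's own
assumptions — not that those assumptions hold in any particular field
dataset.

Two subtleties surfaced while validating recovery. First, estimated cell
F converges to ≈ 0.28 when 0.3 is planted, precisely because He is the
uncorrected plug-in estimator (downward bias ~1/(2n) inflates Ho/He);
this is the behavior of the conventional definitions, not an
implementation artifact, and it sits comfortably within the ±0.05
recovery band at 20-tree cells. Second, mixed-ancestry cells show
positive F without any inbreeding (the Wahlund effect), so the
inbreeding-recovery checks use a single-gene-pool landscape where the
planted F is the only signal.

## Problem sizes and determinism

The test suite and the reproduction script run at the sizes the analyses
were designed around: full 1,504-tree landscapes for the re-sampling
identities (which are exact combinatorics and fast), 500–800 trees for
statistic-recovery checks, 240–600 trees with K scanned over 1–4 and 4–5
EM restarts for the clustering recovery, and 1e5-draw Monte-Carlo
rarefaction oracles on cells of at most 8 trees. Every stochastic step
takes an explicit integer seed, and the pipeline writes a manifest of
output checksums; identical seeds yield identical manifests.

## Limitations

Distances are planar in decimal degrees throughout (neighborhood,
buffers, regions), matching how the grid and diameter are specified; at
high latitudes a degree of longitude shrinks and the "circular"
neighborhood becomes elliptical on the ground. The admixture EM explores
modes less thoroughly than long MCMC runs on weakly structured data. The
climate-envelope scorer is intentionally naive — supply a proper modeled
surface for real coverage analyses. Per-cell statistics carry no
uncertainty estimates; repeated-subsampling corrections beyond rarefied
Na are out of scope.
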