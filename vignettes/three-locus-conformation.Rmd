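---
title: "Methods: three-locus 3D-FISH conformation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: three-locus 3D-FISH conformation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TriLociFISH)
```

# The measurement model

A three-colour 3D-FISH experiment on a gene-dense domain (the motivating
case is the MHC, probed at one gene per class region) yields, per nucleus,
up to six fluorescent spots: two alleles times three loci. The package
works on tabular spot records — nucleus id, condition, species, nucleus
center and radius, and per spot a channel label, a 3D centroid in
micrometres and a spot radius. Nuclei are treated as spheres; the
"local radius" of a spherical nucleus is its radius, and an ellipsoidal
envelope option (`semiaxes` in `radialPosition()`) computes the local
radius along the center-to-spot ray for flattened nuclei. All
normalized quantities are computed downstream from physical coordinates
and never stored as inputs.

Two normalizations make cells of different sizes comparable:

* radial positions are divided by the nucleus radius, so 0 is the center
  and 1 the periphery;
* pairwise spot distances are divided by the nucleus diameter. The
  diameter of the equivalent sphere is used rather than any per-ray
  "local diameter": a two-point segment has no single ray to the
  envelope, so a per-ray definition would be ill-posed, and a per-cell
  size correction is the intent of the normalization.

# Radial statistics

For points uniform in a sphere the normalized radial distance has CDF
$P(X < d) = d^3$; this analytic null is overlaid on the empirical
cumulative frequency curves (`randomRadialCdf()`, `empiricalCdf()`,
`plotCumulativeFrequency()`).

Group comparisons (`compareSamples()`) default to the two-sided
pooled-variance Student t-test **on the raw measurement values**. Testing
the cumulative curves pointwise instead would pseudo-replicate (many grid
points per cell), so the per-cell values are the unit of analysis. Welch
and Kolmogorov-Smirnov variants are provided because the pooled-variance
choice is a convention, not a law; no multiple-testing correction is
applied by default (raw pairwise p-values are reported), with an optional
Holm flag in `pairwiseComparisons()`.

# Triangle metrics

Pairwise normalized distances are labeled a (class I–class II),
b (class II–class III), c (class I–class III). Internal angles follow the
law of cosines with the vertex convention **A at the class III vertex,
B at class I, C at class II** — each angle is opposite the same-letter
side, but the label refers to the vertex (gene), which is worth stating
because readers often expect angle labels to name sides.

Degenerate inputs are resolved by continuity rather than by error:

* a collinear triple (one side equal to the sum of the others) gives 180°
  opposite the long side and 0° at the other two vertices — the direct
  law-of-cosines limit;
* a side of exactly zero length gives 0° at the vertex opposite it and
  90° at each of its endpoints, the limit of an isoceles triangle whose
  base shrinks to a point ($\cos A = \varepsilon/2 \to 1$ shows the
  vanishing side's opposite angle goes to 0, and symmetry forces 90/90);
* the all-zero triangle returns 60/60/60 by scale invariance.

Angles are invariant to the normalization constant, which the tests
exercise by joint rescaling.

Whether triangles should be computed per allele or pooled per nucleus is
not determined by the data model; the package computes per allele and
offers a pooled per-nucleus mean (`triangleMetrics(pooled = TRUE)`).

# Allele pairing and compaction classification

The pairing of six spots into two alleles is not observable directly, so
it is inferred: among the four one-per-channel partitions into two
triplets, the one minimizing the total within-triplet pairwise distance
is chosen (`pairSpots()`). The rule is deterministic and brute-forceable,
and the test suite checks it against exhaustive enumeration on every
synthetic nucleus. A nucleus is excluded when the best and second-best
scores differ by less than a relative `separabilityMargin` (default 0.2):
"clearly differentiated alleles" becomes an explicit, auditable margin.

Compaction uses physical distances, because the threshold is physical:
two loci are separated when their center distance is at least the sum of
the two spot radii ($r_1 + r_2$; $2r$ when a single radius is supplied).
An allele is decompacted (D) when all three pairs are separated,
compacted (C) when none is, and **ambiguous** otherwise. Mixed-pair
alleles are excluded by default (with a reason log); a majority-vote rule
is selectable (`classifyAllele(rule = "majority")`) for users who prefer
to keep every nucleus. Nucleus patterns are unordered pairs of states;
any ambiguous allele excludes the nucleus from pattern counts.

Under the null hypothesis that each allele independently has probability
1/2 of being decompacted, enumeration of the four state pairs gives
P(C-C) = P(D-D) = 1/4 and P(C-D) = 1/2. Observed counts are tested with
the Pearson goodness-of-fit statistic (no continuity correction), and
resting-versus-activated pattern distributions with a 3x2 contingency
chi-squared (df = 2), warning when an expected count falls below 5.

# The survival-zone model

Each locus i is assumed to occupy a sphere of radius $R_i$ ("survival
zone") across the population of fixed cells; cell-to-cell variation in
the pairwise distances then reflects the zones' sizes. For two loci with
zone-center separation $c_{ij}$, the observed distance lies in
$[c_{ij} - R_i - R_j,\; c_{ij} + R_i + R_j]$, so

$$R_i + R_j = \tfrac{1}{2}(d_{ij}^{max} - d_{ij}^{min}), \qquad
  c_{ij} = \tfrac{1}{2}(d_{ij}^{max} + d_{ij}^{min}),$$

and solving the three pair-sum equations yields the closed-form radii
implemented in `szRadii()` (the pair-sum identity holds algebraically for
any extremes and is the module's core regression test). Distances fed to
the module are diameter-normalized by default, consistent with fitted
radii below 0.5. Extremes are pooled over both alleles by default — the
normalization is per cell and nothing distinguishes the alleles — with a
per-allele flag (`fitSurvivalZones(allele = 1)`).

**Why the default fit is maximum likelihood, not raw extremes.** Near
either support endpoint the distance density vanishes like a cubic (both
points must fall in vanishing spherical caps), so the tail CDF behaves
as $\varepsilon^4$ and the sample min/max converge at rate $n^{-1/4}$,
biased inward. At 2000 cells this bias is of order 10% of a typical
radius, and the extreme's sampling noise is of the same order — an
irreducible floor for any estimator anchored on a single order
statistic. The package therefore keeps the closed form as initializer
and diagnostic (`method = "extremes"`, always stored in the model
object) and, by default, refines it by maximizing a binned likelihood
under the same uniform-sphere model. The distribution of the distance
between uniform draws from two spheres a distance c apart is exact and
cheap to evaluate: the difference vector has a radially symmetric
density proportional to the sphere-intersection volume, and a 1D
quadrature over its modulus gives the CDF. The likelihood uses
quantile-spaced bins with finely resolved 2% tails (the endpoints carry
the information about the radii), a joint triangle-inequality constraint
on the three center distances (without it, near-overlapping zones admit
inconsistent per-pair optima), Nelder-Mead on log-parameters, and three
starts around the closed-form estimate. This restores $n^{-1/2}$
convergence: at 2000 cells x 2 alleles the radii (0.10, 0.25, 0.40) are
recovered to a few percent (about 2% at the acceptance seed), where raw
extremes typically err by ~12%.

A `q`-quantile trimming option replaces strict min/max with the
(q, 1-q) empirical quantiles as a robustness guard against gross
outliers; q = 0 remains the default. Negative closed-form radii (possible
under noise) are clamped to zero with a warning, keeping the raw values
for diagnostics.

Zone centers are placed in a canonical 2D frame (r at the origin, g on
the positive x-axis, b in the upper half-plane by trilateration). For
each cell, the triangle defined by its distance triple is embedded in 2D
and aligned to the zone centers by orthogonal Procrustes — rotation,
translation, and reflection if it lowers the residual (the 2D embedding
has a chirality the data cannot fix). This reconstruction is this
implementation's definition; per-cell residuals and the fraction of
points outside their zone circle are reported as model diagnostics.
`positionDensity()` renormalizes `MASS::kde2d` grids so each locus
integrates to one.

# The synthetic-data generator

`simulatePopulation()` emulates the study conditions the analysis
assumes: 60–88 nuclei scored per condition (default 75), near-spherical
nuclei (radius 5 ± 0.25 um, matching a stack of 45 z-planes at 0.244 um),
two alleles per nucleus with three loci each, loci drawn uniformly inside
survival-zone spheres (defaults 0.8, 0.6, 1.0 um with centers well inside
the nucleus; allele 2 is the point reflection of allele 1), BAC-like spot
radius 0.25 um, Gaussian localization noise of 0.05 um per coordinate,
and equiprobable allele compaction (`fracDecompacted = 0.5`).

Design points worth making explicit:

* **Uniform within-zone sampling is an assumption.** Confinement says
  nothing about the within-zone distribution; uniform is the simplest
  choice and is what the fit assumes. Passing tests show the estimators
  recover the generating model, not that real chromatin is uniform in a
  sphere.
* **Compaction is imposed geometrically** by scaling the locus triplet
  about its centroid to the intended side of the threshold (compacted:
  max pairwise distance at 80% of threshold; decompacted: min at 125%,
  capped so loci stay inside the nucleus), so ground-truth labels are
  unambiguous. This deliberately distorts the pure sphere model when the
  threshold is large relative to inter-zone gaps; recovery tests
  therefore use a negligible spot radius where no rescaling triggers.
* **Activation** rotates the two loci of the configured pair (default
  class I–class III) about the third locus, opening the angle at the
  pivot: exactly the named pairwise distance lengthens (default by
  0.6 um, about 0.06 normalized — the magnitude of reported
  activation-induced decompaction) while the other two distances of the
  allele are unchanged. A naive push-apart along the pair axis leaks a
  systematic change into the other distances through the fixed zone
  geometry.
* **Reproducibility**: the seed is mandatory and each nucleus draws from
  its own sub-stream (`seed + condition offset + nucleus index`), so
  adding nuclei or switching condition never perturbs earlier draws;
  reruns are bit-identical.

What the generator does not emulate: chromatin polymer physics,
point-spread-function optics, spot-detection failures, segmentation
errors of the nucleus envelope, or inter-nucleus correlation. Rendered
image stacks (`renderImage()`) are anisotropy-aware Gaussian blobs with
HWHM equal to the spot radius on the confocal voxel grid
(0.079 x 0.079 x 0.244 um), with optional Gaussian and Poisson noise;
`detectSpots()` is a minimal thresholding detector (26-connected
components, intensity-weighted centroids, equivalent-sphere radii), a
stand-in for full segmentation software, matched to the renderer so the
round trip recovers centroids within one voxel per axis.

# Numerical choices and degenerate inputs

* Voxel indices are 0-based with a voxel-center physical convention:
  physical = (index + 0.5) x voxel size.
* Spot pairing with a zero best score guards the relative margin with
  machine epsilon; exact ties are rejected as not clearly differentiated.
* `szCenters()` rejects center distances violating the triangle
  inequality beyond a relative 1e-6; the trilateration y-coordinate is
  clamped at zero for marginally negative discriminants (collinear
  layouts are legal).
* Triangle-inequality violations in per-cell reconstruction skip the cell
  (logged in an attribute) rather than aborting the population.
* The pair-distance CDF quadrature uses 400 nodes; halving it changes
  fitted radii in the third decimal but was kept at 400 for headroom on
  the smallest radius.
* Constant-sample t-tests (zero variance in both groups) return p = 1
  for equal means and p = 0 otherwise instead of erroring.
* qPCR efficiencies outside (1, 2.5] are errors; outside [1.8, 2.2]
  warnings. The Pfaffl ΔCt convention is calibrator minus sample.

# Problem sizes

The test suite and acceptance script use: 2000 cells x 2 alleles for
zone-radius recovery; 5000 points for the radial null; 1000 replicate
null populations of 75 nuclei for the type-I rate of the pattern test;
2000 replicates of n = 20 for the t-test level; 75 nuclei per condition
for the end-to-end activation check; 400 nuclei for the pipeline-level
recovery check. These sizes put Monte-Carlo noise comfortably inside the
asserted tolerances while keeping a full run to a few minutes.

# Known limitations

* The survival-zone model assumes static spheres sampled independently
  across fixed cells (a population-snapshot reading, which is what fixed-
  cell FISH measures); it cannot distinguish motion within a cell from
  cell-to-cell heterogeneity of a static position.
* Whether extremes should be taken over cells only or cells x alleles is
  a modeling choice; both are available, pooled being the default.
* The smallest zone radius is intrinsically the hardest parameter: its
  information sits in the distance-distribution tails, and its relative
  error is several times that of the larger radii at equal n.
* The 2D reconstruction discards one degree of freedom per cell
  (chirality) and has no unique solution when a cell's triangle is
  degenerate.
* Published experimental values for any particular study depend on that
  study's raw measurements and are not reproduced here; the package's
  validation is against its own generative model.
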