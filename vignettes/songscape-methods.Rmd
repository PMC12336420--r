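---
title: "Methods: landscape resistance and repertoire divergence in songscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: landscape resistance and repertoire divergence in songscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(songscape)
```

## The question and the model

Song in oscine birds is learned. Where individuals stop moving between
populations, repertoires diverge by cultural drift, so the *dissimilarity*
of two sites' syllable repertoires should track how hard the intervening
landscape is to cross. `songscape` operationalizes this as an
isolation-by-resistance analysis: a per-species conductance surface, a
circuit-theory pairwise resistance between focal landscapes, Sørensen
β-diversity of syllable presence sets, and a one-predictor Gaussian
regression of β-diversity on resistance versus on geographic distance.

The package assumes: (i) syllable presence/absence per site is the right
resolution for repertoire comparison (abundance-weighted indices are out of
scope); (ii) movement cost is adequately captured by a static [0, 1]
conductance per cell; (iii) sites are far enough apart that recorders
sample distinct populations.

## Conductance surfaces

Cell conductance is the product of two [0, 1] coefficients:

* **Land-cover permeability** — an expert panel's probability that the
  species uses or crosses the cover class. Panel mean and SD per class.
* **Malaria survival** — elevation-banded: year-round transmission below
  900 m, seasonal between 900 and 1500 m, essentially none above 1500 m.
  Band edges are half-open, with 900 m and 1500 m both assigned to the
  seasonal band; verbal band definitions leave the exact boundary
  assignment open, so this is a documented package convention.

Multiplication is itself a convention — nothing forces a particular way of
weighting one coefficient by the other. We multiply because both behave like
survival probabilities and the zero annihilator is semantically right: a
cover the bird will not enter, or a band where malaria kills all
individuals, must zero the cell regardless of the other factor.

Sensitivity variants take each coefficient at its panel mean, mean − 1 SD,
or mean + 1 SD, clipped to [0, 1] (`coefficient_variant()`). The variants
are *not* the min/max of raw expert answers; the ±1 SD reading keeps the
three surfaces ordered cell-wise, which in turn orders the three resistance
matrices (Rayleigh monotonicity), a property the test suite checks.

## Circuit solver

`raster_to_graph()` turns every positive-conductance cell into a node.
Orthogonal neighbors get edge conductance equal to the *mean of the two
cell conductances*; diagonal neighbors (8-neighborhood, the default) get
that mean divided by √2 to reflect the longer span. Averaging conductance
rather than resistance, and the 8-neighbor default, mirror the conventions
of the established circuit-theory connectivity tools; both are arguments,
not constants.

`effective_resistance()` collapses each focal region to a supernode (zero
internal resistance — the region convention of those same tools), grounds
one terminal, injects unit current at the other, and solves the reduced
Laplacian system with a sparse Cholesky factorization (the reduced
Laplacian of a connected component is symmetric positive definite, so a
direct sparse solve at machine precision replaces an iterative method).
The returned potential difference is the effective resistance.
`effective_resistance_pinv()` keeps a dense eigendecomposition route,
`R = (e_A − e_B)ᵀ L⁺ (e_A − e_B)`, used as an internal cross-check and
practical up to a few thousand nodes.

Degenerate inputs: an all-zero raster is an error; terminals in different
components return `+Inf` with a warning rather than an error, and the
regression stage later drops non-finite pairs while reporting how many
were used. Region rasterization uses cell centers; a region that captures
no positive-conductance cell is an explicit, named error.

Resistance units are conductance⁻¹ on the chosen raster discretization.
Absolute values therefore depend on cell size and grid resolution;
only comparisons within one grid are meaningful, which is why the
regression's affine invariance (R² and p unchanged under predictor
rescaling) matters.

## Site geometry

Focal regions are unions of recorder-buffer disks: buffers merge when they
overlap (components of the disk-overlap graph), giving one possibly
multi-part region per site. The disk-set representation is exact for the
quantities the pipeline needs — point-in-region tests and minimum
edge-to-edge distances have closed forms — while areas of merged parts are
integrated on a fine grid (step radius/128; single disks are exact πr²).
Generic polygon regions are supported for the same operations when a
digitized outline replaces buffers. Pairwise distance defaults to the
minimum boundary separation (a shortest linear distance between landscapes
leaves the endpoints unspecified; centroid mode is provided for
sensitivity, and centroid ≥ edge always). The buffer radius is a per-species input — the species' maximum
distance moved — with no hard-coded default for real data.

## Repertoire metrics

Syllables detected exactly once in the whole study are removed before any
analysis; site presence is the OR over the site's recorders. The Sørensen
index is computed with S<sub>k</sub>, S<sub>l</sub> as *total* site
richness. Descriptions of this index sometimes gloss S as per-site exclusive
counts, but that literal reading can go negative, while the total-richness
reading is the classical Sørensen index and matches vegan's binary
Bray-Curtis; we treat the exclusive gloss as a slip and keep a
`literal_exclusive` argument so the alternative is one flag away.
Exclusive-syllable percentages round half-up to one decimal, matching the
summary-table formatting they emulate.

## Community inference

The multivariate comparison fits, for each syllable, a Bernoulli occurrence
model with a group effect, and sums the per-syllable likelihood-ratio
deviances (closed form from the 2×2 table, with 0·log 0 = 0). Inference
permutes recorder-to-group labels — exact under exchangeability — with the
add-one convention p = (1 + #{perm ≥ obs})/(1 + n_perm). The reference
multivariate-abundance tooling defaults to PIT-trap residual resampling
instead; published p-values from that route are therefore comparable in
spirit, not digit-for-digit. The sampling unit is the recorder (six per
site, placed ≥ 1 km apart for independence). Ordination is a column-
centered, unscaled PCA of the site × syllable presence matrix.

## Linkage regressions

The Gaussian identity-link GLM with one predictor *is* ordinary least
squares, so the slope, its two-sided t test on n − 2 degrees of freedom,
and R² are computed in closed form from the normal equations; `stats::lm`
and `stats::glm` serve as test oracles only. The ten pairwise observations
from five sites are not independent; we keep the simple GLM deliberately
(it is the analysis being replicated) and expose `mantel_p()` — a
site-identity permutation — as a clearly separate robustness diagnostic.
Pairs with infinite resistance are excluded and counted. R² is the
ordinary coefficient of determination, which for a Gaussian identity GLM
coincides with the deviance-based pseudo-R².

## The synthetic generator

The generator emulates the study design end to end on a volcanic island:

* **Elevation**: pointwise maximum of linear cones
  (`peak × max(0, 1 − d/radius)`); the default five cones echo a
  Big-Island-like profile (two ~4100–4200 m shields plus three flank
  volcanoes) on a 60 × 60 km grid of 1 km cells.
* **Land cover**: elevation bands (class 1 lowest — non-native lowland
  vegetation through native upland forest) plus uniform patch noise with
  probability 0.15 per cell; 6 classes by default.
* **Expert tables**: 9 raters; each answer a Beta draw with concentration
  25 around a per-class archetype mean rising with elevation band, and
  malaria-survival archetypes 0.15/0.55/0.95 for the three bands.
* **Recorders**: 5 sites × 6 recorders, ≥ 1 km apart inside a 3 km site
  disk, placed by bounded rejection sampling (explicit failure if the
  constraint cannot be met). Site centers are spaced at least
  2(site radius + buffer radius) + one cell, so focal regions of distinct
  sites are disjoint and can serve as circuit terminals.
* **Repertoires**: a latent Gaussian copula. For each of M = 200 pool
  syllables a zero-mean unit-variance latent vector across sites has
  correlation exp(−λ·R<sub>kl</sub>), diluted by independent per-site
  noise of SD 0.3; presence is latent > Φ⁻¹(1 − p) with occupancy
  p = 0.4 (site richnesses of roughly 40% of the pool match the observed
  site-to-total ratios the design emulates); each recorder detects a
  locally present syllable with probability 0.7, producing realistic
  partial detection and singletons.

The copula was chosen because the source describes no generative model and
this one has a closed-form independence limit usable as an oracle:
with independent sites, E[J] = Mp² and E[S] = Mp, so expected Sørensen is
1 − p (0.5 at p = 0.5). More generally `expected_sorensen(rho, p)`
evaluates 1 − P(both latent > threshold)/p by 1-D quadrature of the
bivariate-normal orthant probability; these analytic values ship as the
scenario's ground truth. `exp(−λR)` on a metric need not be positive
definite for every λ, so the correlation matrix is repaired by eigenvalue
clipping at 1e-8 (with a warning) before the Cholesky draw.

What the generator does *not* emulate: individual-level repertoire
variation (sharing is modeled at the population level only — with
autonomous recorders one cannot tell whether exclusive syllables belong to
many individuals or one), observation-duration effects, misclassification
of syllables, and realistic vegetation mosaics. Passing tests therefore
demonstrate the *pipeline's* correctness and statistical calibration, not
that real repertoires follow a Gaussian copula.

## Validation scenarios and problem sizes

The suite's heavier checks and the sizes we settled on:

* Circuit solver versus the dense pseudoinverse oracle on random graphs and
  raster grids up to 100 nodes (tolerance 1e-6), plus 200 random instances
  for the triangle inequality and Rayleigh monotonicity.
* Permutation-test calibration: 500 null data sets (two groups of six
  recorders, 25 syllables, 199 permutations); the add-one, tie-respecting
  p-value makes the test slightly conservative (long-run rejection rate
  ≈ 0.045 at α = 0.05).
* Parameter recovery: 100 scenarios of 5 sites × 6 recorders and a
  200-syllable pool. Because ten pairwise points from five sites carry
  heavily correlated noise, a recovery scenario needs a genuinely strong,
  well-spread signal: resistances are laid out along a one-dimensional
  connectivity gradient spanning 0.2–4.2 (`gradient_resistance()`),
  decorrelated from the (independently random) geographic layout by
  construction, with decay λ = 0.6 so latent correlations span ~0.8 down
  to ~0.07. The regression on resistance then recovers a positive,
  significant slope and beats the distance model in essentially all
  replicates; with weakly spread metric resistances the power drops
  substantially, which is itself informative about the design's limits.
* End-to-end toy runs use a 50 × 50 grid with 3 sites — small enough for
  seconds-scale runs while exercising every stage; determinism is checked
  by hashing every artifact of two identical runs.

## Known limitations

* Raster I/O is ESRI ASCII grid only; inputs must share one projected CRS
  in meters. No reprojection, no GeoTIFF.
* Resistance values are discretization-dependent; cross-study absolute
  comparisons require identical grids.
* The permutation community test needs ≥ 2 recorders per group and treats
  recorders as exchangeable under the null; recorder-day units would need
  a different exchangeability argument.
* With five sites the linkage regression has 10 non-independent points;
  its p-values are replicated as-is from the analysis design, and
  `mantel_p()` should accompany any strong claim.
* Disconnected site pairs (infinite resistance) are excluded from
  regressions rather than modeled.
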