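# songscape

Birdsong is a learned, culturally transmitted trait: when landscapes
fragment and individuals stop moving between populations, local syllable
repertoires drift apart just as allele frequencies do. `songscape`
implements an isolation-by-resistance analysis for acoustic repertoires —
the workflow used to ask whether Hawaiian honeycreeper populations on a
volcanic island share fewer syllables when the landscape between them is
harder to cross, over and above plain geographic distance.

It is aimed at bioacousticians and landscape ecologists who have
per-recorder syllable detection tables and land-cover/elevation rasters,
and at methodologists who want a fully synthetic, ground-truthed testbed
for the whole chain.

## What it computes

1. **Conductance surfaces.** Each raster cell gets a movement conductance
   in [0, 1]: the expert-elicited permeability of its land-cover class
   multiplied by an avian-malaria survival coefficient for its elevation
   band (year-round risk below 900 m, seasonal between 900 and 1500 m,
   essentially absent above 1500 m). Mean, mean − SD and mean + SD
   coefficient variants support a sensitivity analysis.
2. **Circuit-theory resistance.** The conductance raster becomes a resistor
   network (8- or 4-neighborhood; edge conductance = mean of the two cells,
   diagonals scaled by 1/√2). Each focal landscape — the merged buffers
   around its six recorders — is collapsed to a supernode, and the pairwise
   effective resistance

   R(A, B) = (e_A − e_B)ᵀ L⁺ (e_A − e_B)

   is obtained by a sparse solve of the graph Laplacian system with unit
   current injected at A and withdrawn at B. All paths contribute, not just
   the least-cost chain.
3. **Repertoire β-diversity.** Detection tables are cleaned (study-wide
   singleton syllables dropped), aggregated to site presence/absence, and
   compared with the Sørensen dissimilarity
   D<sub>kl</sub> = (S<sub>k</sub> + S<sub>l</sub> − 2J)/(S<sub>k</sub> + S<sub>l</sub>),
   with S the site richnesses and J the shared count.
4. **Inference.** Per-syllable binomial deviances summed into a
   multivariate statistic with label-permutation p-values compare whole
   repertoires between sites; PCA ordinates sites; Gaussian one-predictor
   GLMs (closed-form OLS with a t test) relate pairwise dissimilarity to
   resistance (three variants) and to distance.
5. **Synthetic scenarios.** A seeded generator builds the whole study from
   scratch — cone-model volcano elevation, banded land cover, Beta-drawn
   expert tables (9 raters), recorder layouts (6 per site, ≥ 1 km apart),
   and latent-Gaussian repertoires whose cross-site correlation is
   exp(−λ·R) — with analytic expected Sørensen values as ground truth.

## Worked example

A full synthetic run, from volcano to regression table:

```r
library(songscape)

cfg <- scenario_config(seed = 42)   # 60x60 km island, 5 sites, 6 recorders each
run <- run_pipeline(cfg)
run$summary
#> # A tibble: 1 × 7
#>   n_sites total_syllables richness_min richness_max exclusive exclusive_pct
#>     <int>           <int>        <dbl>        <dbl>     <int>         <dbl>
#> 1       5             175           75           96        48          27.4
#> # ℹ 1 more variable: average_dissimilarity <dbl>
run$linkage
#> # A tibble: 4 × 7
#>   predictor  variant   slope p_value r_squared n_pairs significant
#>   <chr>      <chr>     <dbl>   <dbl>     <dbl>   <int> <lgl>
#> 1 resistance mean    0.0857   0.165      0.226      10 FALSE
#> 2 resistance min     0.0496   0.269      0.150      10 FALSE
#> 3 resistance max     0.123    0.116      0.279      10 FALSE
#> 4 distance   n/a     0.00222  0.0503     0.398      10 FALSE
```

Here 175 distinct syllables survive singleton filtering, 27.4% are
exclusive to one site, and neither resistance nor distance reaches
significance — at the default decay the five landscapes are too
well-connected for strong dialect structure.

A strong-gradient scenario shows what recovery looks like when sharing
really is resistance-driven:

```r
r   <- gradient_resistance(5, seed = 7)       # resistances spanning ~0.2-4.2
cfg <- scenario_config(seed = 7, decay = 0.6)
reps <- generate_repertoires(cfg, r)
sm   <- aggregate_by_site(reps$unit_matrix)
d    <- dissimilarity_matrix(sm)
fit  <- fit_linkage(d[upper.tri(d)], r[upper.tri(r)])
fit
#> <linkage_fit> dissimilarity ~ resistance (mean variant)
#>   slope 0.0687 (p = 0.000362), R^2 = 0.813, n = 10 pairs
glance(fit)
#> # A tibble: 1 × 6
#>   predictor  variant  slope  p_value r_squared n_pairs
#>   <chr>      <chr>    <dbl>    <dbl>     <dbl>   <int>
#> 1 resistance mean    0.0687 0.000362     0.813      10
```

The slope is the increase in Sørensen dissimilarity per unit effective
resistance; `autoplot(fit)` draws the pair scatter with the fitted line,
and `autoplot(ordinate(sm))` the PCA of site repertoires.

Real data enter through the same surfaces: `read_ascii_grid()` for
land-cover/elevation rasters, CSV coefficient tables with
`species/class/mean/sd` columns, a recorder CSV for `delimit_sites()`, and
a detection CSV for `filter_singletons()` → `detection_matrix()` →
`aggregate_by_site()`.

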