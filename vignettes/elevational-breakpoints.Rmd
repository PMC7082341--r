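---
title: "Detecting fault-aligned breakpoints in mountain biodiversity and ecosystem function"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting fault-aligned breakpoints in mountain biodiversity and ecosystem function}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elevbreak)
```

## The problem

Mountainsides are natural laboratories: climate, soil, vegetation, and
microbial communities all change with elevation. Most of that change is
gradual, but where an elevational transect crosses a tectonic boundary —
a suture or fault separating terranes with different parent rock — soil
geochemistry can change abruptly, and plant and soil-bacterial communities
and ecosystem functions may change abruptly with it. `elevbreak` implements
a complete analysis for this situation:

1. **Breakpoint detection.** Where along elevation do responses change
   abruptly? (continuous two-segment regression; compositional turnover
   between adjacent elevations; regression-tree split density; cross-mountain
   similarity profiles).
2. **Synthesis indices.** Ecosystem multifunctionality (EMF; the mean
   z-score of many functions) and multidiversity (MD; the mean standardized
   richness of several taxonomic components).
3. **Driver attribution.** How much of the variation in diversity and
   function is carried by contemporary environment (climate, soil pH,
   moisture) versus geological legacy (parent-rock mineralogy, weathering
   indices)? (AICc model averaging, geological-increment regressions,
   variation partitioning, recursive path analysis).

Because real deposited datasets are not shipped with the package, every
stage is exercised against a seeded synthetic generator with a *planted*
fault, so all claims of recovery are checked against known truth.

## The synthetic gradient

`sim_params()` / `simulate_mountain()` emulate a survey of 18 sites
(evenly spaced 700–3760 m by default) with 10 composite plots per site
(180 samples), a fault planted at ψ\* = 2400 m, and:

* **Communities.** Each taxon has a Gaussian (coenocline) niche
  `A exp(-(e-μ)²/2σ²)` with uniform optima (drawn slightly beyond the
  sampled range so edge sites do not face artificially truncated pools) and
  tolerances of 250–550 m (bacteria) or 200–450 m (plants). Each taxon
  belongs to the below- or above-fault pool according to its optimum;
  on the far side of the fault its expected abundance is multiplied by
  `1 - pool_mixing`. The default `pool_mixing = 0.98` encodes near-complete
  pool replacement across the terrane boundary. OTU counts are multinomial
  at a fixed sequencing depth (10,000 reads; rows sum exactly to depth),
  plant counts are Poisson, and each plot's plant inventory carries density,
  coverage, and height attributes.
* **Weathering–diversity link.** Pool gating alone produces a *symmetric*
  richness trough centred on the fault (each side loses the other pool's
  tail taxa), which contains almost no step component. Real terrane
  contrasts are not symmetric: the strongly weathered side filters
  communities toward dominance. The generator therefore raises the
  log-normal abundance dispersion above the fault by `evenness_step`
  (default 0.9), which depresses detected richness there and plants the
  direct weathering → diversity effect that the driver analyses are meant
  to recover.
* **Geology.** Six minerals, eight metals, and the four molar oxide
  proportions entering the chemical index of alteration (CIA) step at the
  fault by `geo_step` (default 3) within-site standard deviations, with
  noise scaled to 10% of each variable's base value (constant coefficient
  of variation) and lithologically coherent step signs for the metals and
  oxides — otherwise independent random signs can make the derived ratios
  (Ti/Fe, Mg/Al, …) cancel across the fault.
* **Climate and soil.** MAT = 25 °C − 0.0055 °C/m · elevation with 0.3 °C
  site-scale noise (deliberately smooth: *no* breakpoint is planted in MAT);
  MAP, pH, and moisture are linear in elevation with substantial plot-scale
  heterogeneity.
* **38 ecosystem functions** in five groups. The 14 plant-biomass functions
  are derived from the simulated plot inventories through the allometric
  equations (`plant_biomass()`), so they inherit the vegetation's elevational
  structure. The other 24 are linear combinations of standardized MAT,
  moisture, total plant biomass, and bacterial richness plus a hinge term
  `b·(e-ψ*)₊` and Gaussian noise (SD 0.5). Functions carrying a planted
  hinge load only on the linear-in-elevation abiotic drivers — loading them
  on the hump-shaped biotic drivers would make the planted breakpoint
  unrecoverable by construction — and 75% of the hinge coefficients are
  negative (magnitudes 1.5–2.5 per km), so the averaged EMF inherits a
  coherent slope change rather than cancelling it.

What the generator does **not** emulate: spatial autocorrelation, read-level
sequencing error, phylogenetic structure, seasonal climate, and
overdispersion beyond the log-normal jitter. Tests passing on these bundles
demonstrate that the estimators recover planted structure under multinomial
sampling noise; they do not certify performance on real soil profiles.

`simulate_two_mountains()` reuses one truth block (fault, niches,
coefficients) for a second mountain with its own site elevations and
independent noise, emulating a regional-consistency comparison between
gradients on different ranges.

## Breakpoint estimation

`piecewise_fit()` fits the continuous broken-stick model
`y = β₀ + β₁e + β₂(e-ψ)₊` by ordinary least squares at every candidate ψ on
a 1-m grid inside the search band (default 1800–3000 m, the elevational
window containing the suture in the motivating system) and keeps the
SSE-minimising ψ. Candidates must leave at least two distinct elevations on
each side. The grid search is evaluated from suffix sums of the sorted data
(closed-form 3×3 normal equations, elevations in km for conditioning), so a
full search costs microseconds and bootstrap/permutation wrappers stay cheap;
a unit test pins it against a brute-force per-candidate `lm` loop.

**Significance.** The classical F-test of the broken stick against a single
line, charging two extra parameters, is *not* used for the reported p-value:
because ψ is estimated by search, the naive F reference distribution is
anti-conservative (the Davies problem). Instead `p_improvement` comes from a
permutation test — residuals of the single-line fit are permuted, added back
to its fitted values, and the full grid search re-run — which holds the
nominal level by construction (the test suite verifies the rejection rate on
200 null gradients). The F statistic itself is still reported.

**Uncertainty.** `breakpoint_bootstrap()` case-resamples (e, y) pairs,
re-runs the grid search, and reports the percentile 95% interval; if more
than 20% of resamples land on a band edge the interval is flagged
`edge-limited`.

**A known limitation.** A continuous broken stick models a *slope change*.
The planted community turnover is a near-discontinuous *step*, and the best
two-segment approximation to a flat–step–flat profile often puts ψ at a band
edge. On default bundles the piecewise fits of DCA axis-1 scores (and
sometimes EMF) therefore sit at 1800 or 3000 m, while the estimators
designed for composition — adjacent-elevation turnover and split density —
localize the fault to within one inter-site spacing. The consensus tables
keep the honest per-facet estimates; interpret band-edge ψ values as "abrupt
change not representable by a slope change".

`adjacent_turnover()` computes, for each pair of elevation-adjacent sites,
the mean between-site Bray–Curtis dissimilarity and a two-group PERMANOVA
pseudo-F, and selects as breakpoint the pair (midpoint inside the band)
maximising the within-band rank sum of the two statistics, breaking ties by
the higher pseudo-F (the joint "highest turnover" rule needs an explicit
tie policy; rank-sum reduces to argmax whenever one pair dominates both).

`split_density()` fits one depth-3 regression tree (variance-reduction
splitting, minimum leaf 5) of each taxon's abundance on elevation, weights
each split threshold by its impurity decrease (normalized within taxon),
aggregates thresholds with a Gaussian kernel (Silverman bandwidth), and
divides by the kernel density of the sampled elevations. This is a
deliberate single-tree simplification of gradient-forest split importance:
with a single predictor there is nothing for an ensemble's variable
decorrelation to do, and one tree per taxon keeps the profile deterministic.

`cross_mountain()` harmonizes two mountains' taxa (outer join, zero fill),
matches sites by nearest elevation within a tolerance (100 m default), and
profiles matched-pair Bray–Curtis similarity; the profile minimum marks the
shared transition. Per focal site of the second mountain it also regresses
similarity to all first-mountain sites below (or above) a supplied
breakpoint on elevation, testing slopes by response permutation.

## Composition and diversity

`bray_curtis()` wraps the standard abundance-based dissimilarity
Σ|x−y|/Σ(x+y). `permanova()` implements the one-way pseudo-F
partition SS_total = (1/n)Σ d²ᵢⱼ with the add-one permutation rule
p = (1+#{F\* ≥ F})/(1+B) and a `≥` tie comparison (conservative); when a
two-group design has few enough distinct label assignments the p-value is
computed by exhaustive enumeration instead. `ordinate_dca()` performs
correspondence analysis by SVD and detrends axis 2 by dividing the axis-1
range into 26 equal segments (the classical default) and centring within
segments. Hill's nonlinear rescaling is *not* applied, so axis units are raw
scores, not SD units; axis 1 is identical to the CA solution, which the test
suite cross-checks in rank against an independent implementation.

`rarefy_counts()` subsamples each sample without replacement to a fixed
depth (10,000 reads by default), dropping — never rescaling — samples below
depth, with a warning. Chao1 uses the classical `S + F₁²/(2F₂)` form with
the bias-corrected `S + F₁(F₁−1)/(2(F₂+1))` when doubletons are absent.
`aggregate_taxa()` reports Proteobacteria at class rank when aggregating to
phylum, reflecting the ecological heterogeneity of proteobacterial classes;
"dominant phyla" are those occupying more than 80% of samples (boundary
inclusive). Multidiversity averages z-scored richness components (sample
SD); a max-scaling mode exists for sensitivity analyses. Plant importance
values average relative density, coverage, and height; when a plot total is
zero that attribute contributes zero and the divisor stays three, keeping IV
comparable across plots. The shrub and herb allometric equations can go
negative for very small plants; biomass is clipped at zero with a warning.

## Multifunctionality

`zscore_table()` standardizes each function with the *sample* SD (n−1), the
convention of the averaging multifunctionality framework. EMF is the row
mean of z-scores, overall and within the five functional groups; group EMFs
weighted by group size reproduce the overall EMF exactly. Missing entries
are deleted pairwise, with EMF set missing below 50% coverage.
`emf_subset_curve()` re-computes EMF on random k-subsets of functions
(k = 10…38 by default, 1000 subsets per k, exhaustive when cheaper) and
records each subset's Pearson correlation with the full EMF. Because EMF is
a mean, the expectation of subset EMF over uniform subsets equals the full
EMF for every sample — the package tests this exhaustively on a 6-function
table — so the curve isolates pure subset-sampling dispersion.

## Driver attribution

Predictors are first **dereplicated**: of any pair with |Pearson r| > 0.7
(strictly), the variable with the weaker absolute correlation to the
response is removed (a keep-first rule is available); the decision log is
returned. `all_subsets_average()` z-scores everything, fits all 2^p subsets
(p ≤ 15), and reports conditional model-averaged standardized coefficients
and relative importances from AICc Akaike weights.

`geo_increment()` asks what the geological block adds: stepwise AIC
(forward+backward from the null) selects a contemporary model; stepwise
augmentation over the geological block (contemporary terms locked in) gives
the richer model and the percent R² increase. Significance, however, is
tested by the nested ANOVA of the selected contemporary model against the
same model plus the *full* geological block: testing stepwise-*selected*
geological terms would be anti-conservative under the null, whereas the
full-block comparison is selection-free on the geological side and holds its
level (verified on 200 null simulations). The same full-block augmentation
is applied to every contemporary subset to report the fraction of models
with a significant geological gain.

`variation_partition()` splits adjusted R² into unique and shared fractions
(a + b + c + d = 1 exactly; the shared fraction may be negative, as usual
for adjusted partitions). `composite_score()` builds block composites as
indicator combinations weighted by multiple-regression coefficients against
the response, re-standardized to SD 1.

`path_fit()` estimates a recursive path model: each endogenous node is
regressed on its parents (all variables z-scored), giving standardized path
coefficients; effects on the outcome are decomposed by path tracing
(total = direct + indirect, computed from (I−B)⁻¹). Model fit is summarized
by the SRMR between observed and implied correlations (residual variances
1−R², observed correlations among exogenous nodes) and by summed
per-equation AIC for comparing alternative diagrams. This deliberately
replaces full maximum-likelihood SEM: it reproduces the composite-variable,
fully recursive structure and the SRMR fit criterion, but it does not
produce χ² or CFI statistics, and latent measurement models are out of
scope. For fully recursive standardized systems the total effect equals the
simple standardized slope, which the tests verify on simulated trivariate
normal data (n = 10⁴).

## Pipeline, reproducibility, and problem sizes

`run_pipeline()` chains rarefaction → diversity/MD → DCA → piecewise fits,
turnover, split density → EMF and subset curve → model averaging,
geological increments, variation partitioning, and the composite path
models, writing TSV/JSON results, a log with every derived seed, and a
machine-readable `summary.json` stamped with a hash of the analysis-relevant
configuration (paths excluded). One master seed drives deterministic
sub-seeds per stage; identical configuration and seed give byte-identical
summaries. Default permutation and bootstrap counts in the pipeline are 199
(standalone functions default to 999), a deliberate balance between Monte
Carlo resolution (p-floor 1/200) and the cost of re-running the full
analysis many times in the test suite; the planted-truth recovery tests use
100 independent bundles and the calibration tests 200 null simulations.

## Known limitations

* Breakpoint p-values are permutation-based and therefore have a resolution
  floor of 1/(B+1).
* The broken stick cannot represent discontinuous steps (band-edge ψ; see
  above).
* PERMANOVA is one-way only, and no dispersion-heterogeneity test is
  provided.
* Split density uses one tree per taxon, not a forest, and depth 3 bounds
  the number of splits per taxon at 7.
* The path machinery assumes acyclic, fully observed (composite or
  measured) variables; no latent measurement error model.
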