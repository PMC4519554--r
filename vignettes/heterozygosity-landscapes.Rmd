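---
title: "Mapping fine-scale genetic heterozygosity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping fine-scale genetic heterozygosity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetscape)
```

## The problem

Population-based cohorts recruited in small, urbanized regions are
routinely treated as genetically homogeneous: model-based clustering
and PCA-type tools rarely find structure at the scale of a single
city and its hinterland. Yet subtle heterogeneity can still exist
there, shaped less by evolutionary forces than by recent migration
and residential preferences. `hetscape` implements a geostatistical
route to detecting and modeling such heterogeneity: summarize the
genetic diversity of each *land unit* (LU; a postal-area-scale
polygon carrying sampled subjects) by its observed heterozygosity,
test the per-unit values for global spatial autocorrelation, regress
them on socio-demographic covariates under spatially autoregressive
residuals, and compare interpolated "genetic landscapes" of observed
and model-predicted values.

## Observed heterozygosity

Genotypes are biallelic SNP codes per subject and locus: 0 and 2 for
the homozygotes, 1 for the heterozygote, NA for a missing call. For
a group of subjects,

$$H_O = \frac{100}{l} \sum_{j=1}^{l} h_j,$$

where $h_j$ is the heterozygote proportion at locus $j$ and $l$ the
number of usable loci. Two conventions matter and are fixed here:

* **Missing data.** $h_j$ uses the non-missing calls of the group as
  its denominator (per-locus complete case); loci with no callable
  genotype in the group are dropped from the average rather than
  imputed. With complete data this reduces to the pooled heterozygote
  fraction, and the test suite checks both routes coincide exactly in
  that case.
* **Scale.** Values are reported in percent (0--100), the scale on
  which landscapes and divergence summaries are expressed.

$H_O$ is invariant to which homozygote is labeled 0 versus 2, and
under Hardy--Weinberg proportions with allele frequency $q$ its
expectation is $100 \cdot 2q(1-q)$ — both are tested properties.
Loci carry an intragenic/intergenic class as metadata; the pooled set
is the default for every computation, with the class filter available
for sensitivity checks.

## Per-unit covariates

Subject records carry a land-unit id, a native flag (born in the
study country), a main-immigrant flag (born in one of the four
countries that dominate the immigrant fraction: Czech Republic,
Romania, Poland, Ukraine by default), age (25--74 years), education
years (8--17) and an education score (0--9). Per unit:

* Age and education variables (`AGE25_39`, `AGE40_54`, `AGE55_74`
  with inclusive bands, `AGE_MEAN`, `EY8_11`, `EY_MEAN`, `EDU_MEAN`)
  are computed on **natives only**; a unit without natives simply has
  no such entries.
* `GER_P` (percent natives among all subjects) and `MAIN_IMP`
  (percent of the major immigrant group among all immigrants) use the
  full per-unit sample. `MAIN_IMP` is **defined as 0** for units
  without immigrants: the alternative of leaving it undefined would
  silently drop those units from every descriptive summary, while the
  observed study tables include them with zeros.

Percentages are kept at full precision internally; an integer
presentation mode (`rounding = "integer"`) reproduces the whole-
percent convention of published cohort tables, and descriptive
statistics computed on that presentation match their printed summary
rows. Model formulas are printed with the field's uppercase variable
tokens; the aliases `BILD_MN`, `EY_MN`, `AGE_MN` and `EA55_74`
sometimes seen in model tables are resolved onto `EDU_MEAN`,
`EY_MEAN`, `AGE_MEAN` and `AGE55_74` rather than treated as distinct
variables.

## Regionalization and spatial weights

All geometry is planar, in projected meters; geographic coordinates
must be projected (e.g. to the local UTM zone) before import.

* **Aggregation** of sparsely sampled units into neighbors is by an
  explicit user mapping, not an automatic sample-size threshold — in
  practice such choices are judgment calls that no single cutoff
  reproduces (a 12-sample unit may be merged while a 9-sample unit is
  kept, depending on geography). Polygons become multi-part
  geometries, counts add, and the merged unit keeps the target's name.
* **Thiessen (Voronoi) polygons** tile the study area from the LU
  centroids, computed by half-plane clipping of the bounding region;
  cell areas must sum to the bounding area (tested to 1e-6 relative).
* **Contiguity** is queen-style: any shared boundary point within a
  snap tolerance (default 1 m, absorbing digitization noise) makes
  two units neighbors. Units left without neighbors are attached to
  their nearest unit when its border lies within the connect
  threshold (default 5 km — negligible in terms of human interaction
  between modern settlements), or declared isolates and excluded when
  beyond the drop threshold (default 10 km). The repair inserts a
  graph edge rather than redrawing polygons: for binary weights the
  two are equivalent, and edge insertion is simpler and reversible.
* **Weights** are binary and symmetric (1 for neighbors, 0
  otherwise), deliberately not row-standardized: with no information
  about the underlying spatial process, the neutral binary coding is
  retained everywhere, including inside the SAR models. The object
  carries the Cliff--Ord sums $S_0 = \sum_{ij} w_{ij}$,
  $S_1 = \tfrac12 \sum_{ij} (w_{ij}+w_{ji})^2$ and
  $S_2 = \sum_i (w_{i\cdot}+w_{\cdot i})^2$; for binary symmetric
  weights $S_1 = 2 S_0$, a tested invariant.

## Moran's I, two nulls

The global statistic on centered values $z_i = x_i - \bar x$ is

$$I = \frac{n}{S_0} \frac{\sum_{ij} w_{ij} z_i z_j}{\sum_i z_i^2},
\qquad E[I] = -\frac{1}{n-1}.$$

Two complementary tests are provided:

* **Randomization-assumption analytic test.** The variance uses the
  Cliff--Ord randomization formula with the kurtosis correction
  $b_2 = n \sum z_i^4 / (\sum z_i^2)^2$, relaxing the normality
  assumption. The formula is the exact variance of $I$ over all $n!$
  assignments of the observed values to the units — the test suite
  verifies this against exhaustive enumeration for $n \le 7$. It
  needs $n \ge 4$ (smaller $n$ zeroes the denominator).
* **Monte-Carlo permutation test.** Values are randomly reassigned to
  units `nsim` times (default 10000) and
  $p = (1 + \#\{I_{sim} \ge I_{obs}\})/(nsim + 1)$, a convention that
  can never return 0. The permutation stream is vectorized and
  seeded, so results are reproducible bit for bit.

The default alternative is one-sided "greater" — positive
autocorrelation is the phenomenon of interest and the convention of
the reference implementations; two-sided and "less" are flags. The
permutation test is calibrated: over 2000 independent null data sets
its size at $\alpha = 0.05$ stays within a point of nominal (tested).

## SAR error models and forward selection

Heterozygosity is regressed on per-unit covariates under spatially
autoregressive residuals:

$$y = X\beta + u, \qquad u = \lambda W u + \varepsilon, \qquad
\varepsilon \sim N(0, \sigma^2 I).$$

The fit maximizes the profile log-likelihood
$LL(\lambda) = -\tfrac n2 \ln(2\pi\hat\sigma^2(\lambda)) +
\ln|I - \lambda W| - \tfrac n2$, where $\hat\beta(\lambda)$ and
$\hat\sigma^2(\lambda)$ are the GLS solutions at fixed $\lambda$ and
the log-determinant comes from the eigenvalues of $W$:
$\ln|I-\lambda W| = \sum_k \ln(1-\lambda\omega_k)$ (verified against
direct determinants up to $n = 12$). $\lambda$ is searched by
Brent-type bounded optimization over the feasible interval
$(1/\omega_{min}, 1/\omega_{max})$ shrunk by $10^{-6}$ at each end; a
boundary estimate triggers a warning. Design choices:

* $\hat\sigma^2$ is pure ML (no degrees-of-freedom correction),
  consistent with the likelihood-ratio construction of the $\lambda$
  test, $2(LL(\hat\lambda) - LL(0)) \sim \chi^2_1$. At $\lambda = 0$
  the fit reproduces OLS coefficients and log-likelihood to machine
  tolerance (tested).
* Covariate p-values are Wald z-tests from the ML covariance
  conditional on $\hat\lambda$,
  $\hat\sigma^2 (X^\top A^\top A X)^{-1}$ with
  $A = I - \hat\lambda W$ — the quantity the reference summaries
  report. With 12 units these are asymptotic and should be read as a
  screening device, which is exactly how the selection rule uses
  them.
* **Forward search**: starting from the intercept model, the
  candidate with the smallest Wald p-value is added at each step, up
  to `max_terms` covariates (default 4, the size of published
  best-model tables). Every visited model whose covariates are *all*
  significant at `alpha` (default 0.05) is retained — the procedure
  deliberately reports a set of admissible models rather than a
  single winner, whose final ranking is delegated to the landscape
  divergence stage. The search is pure forward (no removal steps).
  An empty retained set is a valid outcome.
* `evaluate_added_covariate()` refits a retained model with one extra
  term (e.g. the immigrant-composition variable `MAIN_IMP`) and calls
  it an improvement only when the extra term is significant and every
  original term stays so.

## Genetic landscapes and divergence

Per-unit values are attached to LU centroids to form a point layer;
a unit assembled from many postal areas (the pooled city) can
replicate its single value onto all of its sub-centroids, which
stabilizes interpolation over a disproportionately large polygon
instead of letting one point represent it.

Interpolation uses a **regularized spline with tension**: a
thin-flexible-plate surface $z(p) = a_1 + \sum_j c_j R(r_j)$ with
radial basis $R(r) = -[\ln\rho + E_1(\rho) + \gamma_E]$,
$\rho = (\varphi r/2)^2$, where $E_1$ is the exponential integral and
$\gamma_E$ Euler's constant ($R(0)=0$ by continuity). The
coefficients solve the saddle-point system with `smoothing` added to
the diagonal and $\sum_j c_j = 0$; at zero smoothing the surface
passes through the data points exactly (tested to 1e-6, plus an
independent dense-solve oracle). Numerical conventions:

* **Tension is per map extent**: internal distances are divided by
  the larger side of the data bounding box, so `tension = 40` means
  the same stiffness regardless of whether coordinates span 3 km or
  300 km. Defaults `tension = 40`, `smoothing = 0.1` give surfaces
  that honor the data closely while damping bull's-eyes at these
  point densities; both are user-tunable and reported per run.
* The default grid is 200 square cells across the study bounding box;
  cells outside the unit polygons are nodata and excluded from every
  statistic. Coincident points with conflicting values are an error
  at zero smoothing.

Model goodness is quantified on the rasters. With $max\_rg$ the range
(max minus min) of the observed landscape over its valid cells, the
divergence surface is

$$100 \cdot \frac{|H_O - H_m|}{max\_rg}$$

per cell — the absolute observed-minus-predicted difference as a
percentage of the observed range (dividing by $max\_rg/100$ is the
same thing; the multiplicative form avoids a needless intermediate).
Surfaces are summarized by mean, SD, median, min and max over valid
cells, and models rank by ascending mean with SD as tie-break. Note
that $max\_rg$ is a property of the *interpolated* observed raster:
its extremes need not equal the extreme per-unit values, and the
implementation follows the raster definition.

Rasters are read and written as ESRI ASCII grids (six-line header,
rows north to south) so they interoperate with GRASS-style GIS
tooling; a CSV export of cell centers is also available.

## The synthetic generator

Because cohort genotype data of this kind are not redistributable,
the package ships a generator whose defaults emulate the study
conditions end to end:

* 13 land units on a schematic tiling that reproduces the study
  area's topology — a central city ringed by contiguous suburbs,
  three units within 5 km of the net (repaired by explicit
  connections), one unit beyond 10 km that drops out as an isolate —
  with the published per-unit counts of subjects, natives, immigrants
  and main immigrants (549/179/146 in total over 728). The geometry
  is synthetic; only topology, areas and centroids enter the methods.
* Genotypes drawn under Hardy--Weinberg proportions at 212 loci with
  native minor-allele frequencies uniform on [0.10, 0.50] and an
  average call rate of 97.3 percent. Immigrant genotypes come from a
  pool whose frequencies are shifted a fraction `delta` (default 0.2)
  of the way toward 0.5 — a deliberately transparent single-parameter
  contrast that raises immigrant heterozygosity and makes expected
  values computable in closed form, rather than a coalescent model.
  A spatial gradient in the immigrant fraction thus induces a
  heterozygosity gradient whose detectability the test suite
  measures; `delta = 0` with a flat fraction is the null.
* Unit-level covariate fields (age, education) are perturbed by a SAR
  process with known $\lambda$ (default 0.15) on the region's own
  contiguity weights, so autocorrelation tests and SAR fits have
  recoverable targets. `simulate_sar_outcome()` exposes the exact
  data-generating process matched by the fitter.

What the generator does **not** emulate: linkage disequilibrium
between loci, family structure or cryptic relatedness, genotyping
batch effects, real administrative boundaries, or
isolation-by-distance gradients within units. Passing tests
therefore demonstrate the statistical machinery is correct and
calibrated under the stated model — not that any particular real
cohort satisfies that model.

## Problem sizes and runtime choices

The test suite is sized for a desk-scale run: exhaustive permutation
oracles up to $n = 7$; 2000 null replicates (at 99 permutations
each) for the permutation-test size; 500 replicates for $\lambda$
recovery on a $6\times6$ lattice; 5-point instances for the
interpolation oracle; pipeline smoke runs on 36-column grids with 60
loci. The pipeline defaults (10000 permutations, 200-column grids,
212 loci) remain the recommended analysis settings.

## Known limitations

* Wald p-values and the $\chi^2_1$ likelihood-ratio reference are
  asymptotic; with a dozen land units they are screening tools, and
  the divergence-surface ranking — not the p-values — picks the final
  model.
* Only SAR *error* models are fitted; spatial-lag (autoregressive
  response) models, spatial filtering and information-criterion
  selection are out of scope.
* Contiguity repair assumes the provided polygons are valid and
  non-overlapping; holes in imported GeoJSON are dropped.
* Published per-unit heterozygosity statistics are printed at two
  decimals after percent scaling; reproductions should not chase the
  last digit, which depends on unstated rounding order.
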