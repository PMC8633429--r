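---
title: "Methods: wood-trait variation, plasticity and phylogenetic signal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wood-trait variation, plasticity and phylogenetic signal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oaktraits)
```

`oaktraits` implements the quantitative core of a comparative wood-anatomy
study design: individual trees of many congeneric species are sampled in
plots along an environmental (aridity) gradient, their xylem anatomy is
measured, and the questions are (i) how traits covary and respond to the
environment, (ii) how plastic each species is and what drives that
plasticity, (iii) whether species co-occur more or less than chance, and
(iv) how much of the trait variation is explained by shared ancestry. This
vignette explains each model, its assumptions, the tunable parameters, and
the numerical and design choices made where the methods literature leaves
options open.

## Derived hydraulic variables

From vessel diameter `VD` (µm, the equivalent-circle diameter averaged over
measured vessels) and vessel frequency `VF` (vessels per mm²) the package
derives, per individual:

* vulnerability index `VI = VD / VF` (Carlquist's index: wide, sparse
  vessels are hydraulically riskier),
* relative hydraulic conductivity `RC = r^4 VF` with `r = VD/2` — the
  Hagen–Poiseuille proportionality, reported in raw µm⁴·mm⁻² without a
  viscosity constant because only relative comparisons are meaningful,
* vessel composition index `S = VA / VF` and lumen fraction `F = VF · VA`.

The product `VF · VA` mixes mm⁻² with µm²; `derive_vessel_variables()`
multiplies by 10⁻⁶ by default so `F` is a true dimensionless fraction
(physically interpretable values around 0.1–0.2 for typical oak wood). The
raw product is available via `lumen_fraction_scale = 1` for compatibility
with tabulations that skip the unit conversion. When vessel area was not
measured it is reconstructed as `π (VD/2)²` and flagged: the mean of
per-vessel areas exceeds the circle area of the mean diameter (Jensen's
inequality), so reconstructed areas are biased slightly low and the flag
matters when both kinds of input are mixed.

Degenerate inputs follow one rule: missing measurements propagate as `NA`,
never as zero; `VF = 0` leaves the ratios `S` and `VI` undefined (`NA`)
while `RC = 0` because no vessels conduct nothing.

## Leaf-habit classification

Leaf habit (deciduous / brevideciduous / evergreen) is derived from a
year of canopy-foliage observations. A day counts as *foliated* when
interpolated foliage is at least 50 % of the series maximum — a relative
threshold, so the classification is invariant to how foliage was scored.
Observations are interpolated linearly onto a daily grid with circular
wrap-around (December joins January), which makes leafless spells spanning
the year boundary count correctly. The field definitions are qualitative,
so the day-count cutoffs are explicit, configurable parameters
(`habit_thresholds()`): evergreen requires ≥ 360 foliated days; deciduous
requires a longest leafless spell of ≥ 60 consecutive days; everything in
between is brevideciduous. Series covering less than ~10 months are
extrapolated across the gap and flagged, because the missing months could
hide a leafless spell.

## Environmental variables

The aridity index is `AI = MAP / PET` with the 0.65 humid threshold (and
the finer five-class breakdown available). Potential evapotranspiration
uses the temperature-based Hargreaves–Samani form
`0.0023 · Ra · (Tmean + 17.8) · sqrt(Tmax − Tmin)` per period, scaled by
period length and summed to an annual total; `Ra` must be supplied as its
evaporation equivalent in mm/day.

Collinearity among candidate climate variables is screened by iterated
variance inflation: the variable with the largest `VIF = 1/(1 − R²)` is
dropped until all remaining VIFs are at or below the threshold (default
10). Two choices make the screen deterministic: a perfectly collinear
variable has infinite VIF and is removed first, and ties (including
multiple infinite VIFs) are broken by removing the variable *later* in the
input column order. Reordering inputs therefore cannot change the retained
set except through that documented tie-break.

## Relative distance plasticity index

For one species and trait, RDPI is the mean over all pairs of individuals
growing in *different* plots of the relative distance
`|x' − x| / (x' + x)`. Within-plot pairs are excluded — the index compares
individuals under different conditions — and a pair with both values zero
contributes 0 (the 0/0 case is logged as a definition, not dropped).
For nonnegative traits the index lies in [0, 1]: 0 when the trait is
invariant, 1 exactly when every cross-plot pair has one zero member. It is
invariant to multiplying all values by a positive constant, which the test
suite checks as a property. Species collected in a single plot carry no
cross-environment information and are excluded with a message.

`rdpi_plot_pair_matrix()` resolves the same quantity by plot pair, so the
scalar index equals the pair-count-weighted mean of the matrix entries —
a consistency identity under test. Section-level matrices are entrywise
means over species, ignoring missing entries (a species absent from a plot
leaves that row/column missing); an entry missing in every species stays
missing.

## Multiple regression on distance matrices

MRM regresses the unfolded strict lower triangle of a response distance
matrix (here: arcsine-square-root-transformed RDPI plot-pair matrices) on
predictor triangles (geographic and standardized-Euclidean environmental
distances). Distances are not independent, so ordinary inference is
invalid; instead rows and columns of the *response only* are permuted
jointly, the regression is refit, and P-values are the fraction of
permutations with `|coefficient|` (or `R²`) at least the observed value,
with the +1 correction so P is never zero. The permutation seed is a
required argument: permutation P-values are part of the result and must be
reproducible.

Missing response entries (sparse RDPI matrices) are handled by pairwise
deletion of triangle elements; the usable pair count is reported, and a fit
with fewer usable pairs than coefficients + 2 is an error rather than a
silent near-singular fit. Under permutation the complete-case set moves
with the permuted matrix, which keeps the null exchangeable.

Between-section comparisons of RDPI values use the Welch unequal-variance
t-test (fractional Welch–Satterthwaite degrees of freedom).

## Probabilistic co-occurrence

If two species occupy `n1` and `n2` of `N` plots independently, the number
of shared plots is exactly hypergeometric. `classify_pair()` computes both
inclusive tails (`p_lt`, `p_gt` both include the observed count — the
standard convention for this model, and the reason it is conservative) and
labels the pair positive (`p_gt < α`), negative (`p_lt < α`) or random.
All `C(S, 2)` distinct unordered pairs are evaluated; no pair is filtered
by expected co-occurrence by default (a `filter_expected` flag exists for
compatibility with implementations that drop expectations below 1).
Because the test is exact and discrete, its realized type-I error is below
the nominal α — the calibration test checks the non-random fraction under
a null matrix from above, not as a two-sided band.

## Phylogenetic comparative methods

All tree handling is through `ape`; the statistics are computed in this
package and cross-checked in the test suite against independent dense
matrix oracles (and against `ape::pic`, `picante::Kcalc`,
`phytools::phylANOVA` and `nlme::gls` where those are available).

**Independent contrasts.** Felsenstein's post-order algorithm: contrast
`(x_L − x_R)/√(v_L + v_R)` at each internal node, variance-weighted
ancestral values, and branch extension `v_L v_R/(v_L + v_R)`. Polytomies
are resolved to zero-length binary branches by default (the common
practice); the resolution introduces zero-length internal branches, which
is harmless as long as no *pair* of daughter branches has zero total
variance — that case raises an error. On a binary tree with `n` tips the
`n − 1` standardized contrasts are i.i.d. with variance equal to the
Brownian rate, which the suite verifies by simulation.

**Contrast correlations and PCA.** Contrasts have no defined mean, so
correlations and regressions go through the origin:
`r = Σxy/√(Σx²Σy²)`, significance from the through-origin regression t on
`n_tips − 2` degrees of freedom. The through-origin form is invariant to
paired sign flips, so the (arbitrary) positivization convention cannot
change results. PCA (`trait_pca()`) is an ordinary correlation- or
covariance-matrix eigendecomposition; redundant derived variables (vessel
area and the composition index, which duplicate `VD`/`VF` information) can
be excluded with the `exclude` argument.

**Blomberg's K.** `K = (MSE0/MSE) / E[MSE0/MSE]`, where MSE0 is the tip
variance around the GLS phylogenetic mean, MSE the GLS mean squared error
under the Brownian covariance `C`, and the expectation
`(tr C − n/Σ(C⁻¹))/(n − 1)` is the analytical Brownian value for that
tree. K = 1 is the Brownian expectation; the acceptance suite verifies
that the mean K over 500 simulated Brownian traits on a fixed 50-tip tree
is 1 ± 0.1. The randomization P-value shuffles tip values and asks how
often shuffles give a contrast variance as low as observed — one-sided,
because phylogenetic signal means *lower* contrast variance; a two-sided
version is reported alongside for completeness.

**PGLS.** Generalized least squares with residual covariance fixed
proportional to shared branch length (no Pagel's λ estimation — matching
the default behaviour of the standard tools; λ/κ/δ transforms are out of
scope). The variance scale is profiled by maximum likelihood for the
likelihood and AIC, with `k` = number of coefficients + 1 (the variance)
— stated explicitly because AIC conventions differ; standard errors and
t-tests use the unbiased `n − p` estimate, as `nlme`/`caper` do. On a star
phylogeny the covariance is diagonal and PGLS reproduces OLS exactly (an
identity under test, not an approximation). `pgls_select()` fits one
single-predictor model per environmental variable and returns the
minimum-AIC fit with the full table; `ols_fit()` is the phylogeny-free
counterpart reported side by side, useful because signal estimates are
unstable at small species counts. A response that is an exact linear
function of the predictor gives zero residual variance; the fit is flagged
(`perfect_fit`) and its standard errors withheld rather than reporting
spurious infinite precision.

**Phylogenetic ANOVA.** The observed statistic is the ordinary one-way
ANOVA F. Its null distribution is built by simulating Brownian traits on
the tree and recomputing F per simulation, which accounts for the fact
that species in the same group are phylogenetically clumped. The Brownian
rate is estimated from the data by GLS (with an `n − 1` denominator; F is
scale-invariant, so this choice cannot affect P-values). Post hoc pairwise
t statistics get simulation-based P-values, Holm-adjusted across pairs via
`p.adjust`.

## The synthetic-data generator

No individual-level data ship with the package, so every stage is
validated against `simulate_study()`, whose defaults encode the emulated
study conditions: 21 species on a pure-birth tree (rescaled to unit
height) split into two sections at the root, three leaf-habit classes
assigned with section-biased probabilities, 33 plots on a linear
elevation gradient (650–2738 m) mapped to aridity index 0.78–1.78, five
individuals per species per occupied plot, and 50 per-vessel diameter
measurements per individual with 30 % CV.

Choices where the design was open, fixed once:

* **Occupancy** is a Gaussian niche on the AI axis. Breadth 0.06 AI units
  and amplitude 0.55 give an expected 2–3 occupied plots per species —
  the occupancy implied by a ~275-individual sample over 21 species at 5
  trees per plot. Single-plot species arise occasionally by design; they
  exercise the plasticity exclusion rule. Every species is guaranteed its
  optimum plot so presence rows are never empty.
* **Trait construction** is multiplicative (log scale): species value =
  baseline × Brownian deviation × habit shift × environmental response
  `exp(slope · (AI − midpoint))`, with lognormal individual noise
  (CV 15 %) — traits are positive and right-skewed, and a mean-preserving
  lognormal keeps the configured arithmetic means exact.
* **Climate variables** are generated with fixed strong correlations to
  AI (temperature of the driest quarter negative, wet-quarter
  precipitation positive) so that the VIF screen has realistic
  collinearity to remove.
* **Defaults for rates and slopes** (e.g. height responds +0.35 log units
  per AI unit, wood density −0.15) reproduce the qualitative gradient
  pattern expected of oaks: taller, wide-vesselled, low-density trees at
  the humid end.

What the generator does *not* emulate: spatial dispersal limitation and
biotic interactions (occupancy is environment-only, so co-occurrence nulls
are clean by construction), climate measurement error, within-tree
systematic anatomy gradients, and a realistic oak phylogeny (the tree is
pure-birth; a user-supplied Newick replaces it for real analyses).
Passing tests on this generator therefore demonstrate statistical
correctness of the machinery — recovery of known slopes, nominal error
rates, calibrated K — not that any particular biological conclusion holds
in field data.

`recovery_suite()` summarises one simulated bundle: generating versus
PGLS-recovered environmental slopes and per-trait K.

## Problem sizes and runtime choices

The shipped test suite uses sizes chosen to make every statistical claim
testable in a few minutes on one core: calibration and recovery runs use
200 replicates (type-I error checks compared against the 99 % binomial
band around 0.05, 200-replicate slope recovery with a 5 % bias budget),
the K calibration uses 500 Brownian traits on one 50-tip tree, MRM null
checks use 99 permutations per replicate, and the RDPI effect-size ladder
uses 20 replicates per rung on an 8-species, 12-plot world. Production
analyses should use the method defaults (5000 MRM permutations, 999 K
randomizations, 1000 ANOVA simulations).

## Known limitations

* PGLS offers the Brownian correlation only; no λ estimation means model
  misspecification shows up as inflated signal, which is why the OLS
  counterpart is always reported.
* The MRM permutation scheme permutes the response matrix only; when
  predictors are themselves highly collinear distance matrices, individual
  coefficient P-values inherit the usual multicollinearity caveats.
* The exact co-occurrence model is conservative at small plot counts, and
  with widespread species (occupying nearly all plots) its support
  collapses and almost everything is classified random — a property of
  the model, not a bug.
* RDPI confounds plasticity with within-plot measurement noise; the
  generator's noise-floor property (measured RDPI rises with the
  within-species CV even at zero environmental effect) quantifies this,
  and comparisons should therefore be made at matched sampling effort.
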