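---
title: "Scenario land-use simulation and carbon-storage accounting: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scenario land-use simulation and carbon-storage accounting: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carbonscape)
```

carbonscape couples three models that are widely used together in
land-system science — a patch-generating cellular-automaton land-use
simulation, pool-based ecosystem carbon accounting, and gray
forecasting of carbon densities — and adds the coordination analytics
used to judge whether land-use intensification and carbon storage grow
in balance. This vignette explains each model, the assumptions behind
it, the tunable parameters and their defaults, and the design choices
made where the methods literature leaves the design open.

## The data model

Land use is a categorical raster on a square grid in an equal-area
projection: codes 1–7 for farmland, forests, grassland, wetland,
waters, construction land and unused land. Cell area is computed from
the cell size alone (`(cell_size/100)^2` ha), so the projection is
assumed, not checked — appropriate for the Albers-type grids these
data are distributed in. Nodata cells (outside the basin boundary) are
frozen: never transitioned, never counted. I/O uses the ESRI ASCII
grid format, a plain-text raster with self-describing georeferencing,
which keeps every artifact diffable and the test fixtures generable in
code; round-trips are bit-exact for integer rasters.

## Carbon accounting

Storage is the four-pool linear account

$$CS = \sum_{i=1}^{7} (C_{i,\mathrm{above}} + C_{i,\mathrm{below}} +
C_{i,\mathrm{soil}} + C_{i,\mathrm{dead}}) \times S_i,$$

densities in Mg ha⁻¹, areas in ha, reported in Tg (10⁶ Mg). Waters
carries zero in all pools. Densities are class-uniform: the model
deliberately ignores within-class spatial variation, which is the
standard simplification of pool-based accounting and its main known
limitation. Two computation paths (per-class areas, per-cell map) are
maintained and tested to agree to 1 part in 10⁶.

Transition flows decompose a storage change by land conversion:
`area(i→j) × (density(j) − density(i))`, reported in 10⁴ Mg. By
default both classes are priced at horizon-year densities, isolating
the land-change effect from the density trend; a flag prices the
source class at start-year density instead. The choice matters only
for the split, not the total.

The bundled Dongting Lake Basin tables (`dlb_carbon_density()`,
`dlb_class_areas()`) carry the basin's published per-class areas for
2020 and four 2030 scenarios and the four-pool densities for 2020 and
2030; they are the desk-scale reference inputs for the acceptance
checks.

## GM(1,1) gray forecasting

Future densities come from the first-order, one-variable gray model.
With the accumulated series $x^1 = \mathrm{cumsum}(x^0)$ and
background values $z^1(k) = (x^1(k) + x^1(k-1))/2$, least squares on
$x^0(k) = -a\,z^1(k) + b$ gives the development coefficient $a$ and
gray action $b$; restored values
$\hat x^0(k) = (x^0(1) - b/a)(1 - e^a)e^{-a(k-1)}$ forecast the
series, anchored at the first observation, with $a = 0$ handled as the
constant limit $b$. The model is defined only for strictly positive
series of length ≥ 4. For an exact geometric input $c\,r^{k-1}$ the
normal equations solve in closed form to $a = -2(r-1)/(r+1)$,
$b = 2c/(r+1)$ — the package's tests pin the fit to this closed form
at 10⁻⁹. Note the restored values follow $e^{-a(k-1)}$, not
$r^{k-1}$: the in-sample error vanishes only in the near-stationary
limit $r \to 1$, which is the regime decade-scale density series
occupy.

## Demand projection

The natural-evolution demand is the Markov projection
$\mathbf{a}_{t+1} = \mathbf{a}_t P^n$, with $P$ the row-normalized
historical transition crosstab (empty classes get identity rows).
Row-stochasticity conserves total area, and projection satisfies
Chapman–Kolmogorov to 10⁻⁹. A per-class ordinary-least-squares linear
trend is computed alongside as a cross-check; because the literature
names both without stating the combination, a blend weight is exposed
and defaults to 1.0 (pure Markov). Negative linear extrapolations are
clamped to zero with the shortfall redistributed proportionally so the
total is conserved. Demand in hectares is converted to whole cells by
largest-remainder rounding against the mapped cell count.

## Development probabilities (land-expansion analysis)

For each class, the cells that converted *to* that class between the
two historical dates are the positives; negatives are uniformly
sampled unconverted cells at a 1:1 balance (configurable). A
random-forest probability ensemble (100 trees by default, single
thread for determinism, via the `ranger` package) maps driver values
to expansion probability, and the trained model is evaluated at every
mapped cell to give the per-class development-probability surface.
One binary model per class, rather than one multiclass model, mirrors
the expansion-analysis design. Driver importance is reported but not
used for selection. Classes with no observed expansion get an all-zero
surface and an explicit signal. Sampling rates and tree counts are not
prescribed by the source methods, so they are exposed as arguments.

## Patch-seeding allocation

The automaton converts cells until each class's count is within
tolerance of demand. Each sweep:

* classes above demand are donors, classes below are receivers — a
  cell may leave its class only while it is over-allocated and join
  one only while under-allocated, which makes every per-class absolute
  demand gap non-increasing (a tested invariant) and conservation of
  the mapped cell count structural;
* the score for converting cell $x$ of class $f$ to receiver $j$ is
  $P_j(x)\,\Omega_j(x)\,I_j\,M_{f,j}$, where $\Omega_j$ is the
  fraction of class-$j$ cells in the Moore window (radius 1 by
  default, center excluded, per-class weights default 1), $I_j$ an
  adaptive inertia multiplied by $1+\varepsilon$ when $j$ is
  under-allocated and divided when over-allocated
  ($\varepsilon = 0.1$), and $M$ the scenario multiplier matrix;
  forbidden transitions and restricted cells score zero;
* cells with zero neighborhood support can still convert by random
  patch seeding: with probability $\mu_j = 0.02$ and development
  probability above a threshold that starts at 1 and shrinks by
  $\delta = 0.9$ each sweep, the development probability replaces the
  neighborhood term — this is what lets new patches nucleate away from
  existing edges;
* each donor cell draws one candidate class by roulette wheel over its
  scores; proposals are accepted in decreasing score order while donor
  surplus and receiver need remain.

Score-ordered acceptance (rather than random order) concentrates
conversion where evidence is strongest and makes patch growth
coherent; the stochastic elements are the roulette draw and the
seeding lottery, so identical inputs and seed reproduce the map
exactly (tested). Demand tolerance defaults to
`max(1 cell, 0.1% of class demand)` because exact equality can be
infeasible under constraints; infeasibility (e.g., all transitions
forbidden) terminates with a diagnostic naming the unmet classes after
25 sweeps without progress. The `max_loss` argument caps conversions
away from each class, which is how the planned-development intensity
cap is enforced. None of the window radius, weights, $\mu$, $\delta$
or $\varepsilon$ are prescribed in the source methods; the defaults
above are the package's own and all are config-exposed.

## Scenario rules

Scenarios are declarative and compiled against the base map:

* **nes** — identity multipliers, no masks (the compiled invariant).
* **eps** — ×1.6 on farmland/unused → forests/wetland/waters and
  grassland → forests; ×0.2 on farmland/unused → construction;
  forests/grassland/wetland/waters frozen inside the
  ecological-barrier mask, except within a 10-km buffer of existing
  construction kept open for minimum urbanization.
* **eds** — ×1.5 on everything except waters → farmland/construction;
  waters frozen.
* **pds** — forests/wetland/waters frozen in barrier masks, farmland
  frozen in basic-farmland masks, and a 6.9% per-class development
  intensity cap outside restrictions.

"Improving a transition probability by 60%" is read multiplicatively
(×1.6) on allocation scores — the relative phrasing, and it keeps
scores in a valid cone. The multipliers also feed demand: the Markov
row probabilities are multiplied and renormalized before projection,
so policy pressure acts on both paths (either can be disabled by
passing the unadjusted model or identity multipliers). Whether the
intensity cap is per class or on the total is ambiguous in planning
practice; per class is the default with `cap_total` as the switch.
Barrier and basic-farmland masks are user-supplied layers — digitizing
planning polygons is out of scope, and toy masks are built in code in
the tests.

## Validation metrics

Overall accuracy is the confusion-matrix trace share; Cohen's kappa is
$(p_o - p_e)/(1 - p_e)$ with $p_e$ from marginal products (undefined,
with an explicit signal, for a single-class matrix). The figure of
merit is computed on change space: among cells where change was
observed or simulated, hits (correct new class) over
hits + misses + wrong-class hits + false alarms. Both are pinned to
brute-force enumerations of their definitions in the tests. Nodata is
excluded everywhere.

## Coordination analytics

Land-use intensity per block is the level-weighted area sum (levels 1
unused … 4 construction). Growth rates are simple annualized relative
changes — the coordination index is scale-invariant, so the
simple-vs-compound choice only affects sub-labels near zero, and a
`compound` flag is provided. The index

$$O = \frac{|(A_{LUI} + A_{CS})/2|}{\sqrt{A_{LUI}^2 + A_{CS}^2}}$$

is 1 exactly on the balanced diagonal and 0 under exact opposition.
Blocks are 3 km by default. Classification thresholds: $[0, 0.5)$
uncoordinated, $[0.5, 0.8)$ adapted, $[0.8, 1]$ coordinated — the
published class table leaves 0.8 itself unassigned; it is assigned
upward here as a measure-zero boundary convention. Sub-labels: "ahead"
when carbon-storage growth leads, "lagging" otherwise, equal rates
labelled ahead by convention. Blocks with a zero base value and
positive end value have undefined growth; they are reported as a
separate "no-change" category and excluded from the ellipse.

The standard deviational ellipse uses the weighted mean center, the
standard arctangent rotation formula, and semiaxes equal to the
weighted standard deviations along the rotated axes (`scale = 1`; the
√2 coverage variant is available via `scale`). The axes equal the
square roots of the weighted covariance eigenvalues — the test
oracle — and the angle is clockwise from north. A related published
"oblateness" quantity equals twice the minor semiaxis rather than any
geometric oblateness, so it is not implemented as a named output.

## The synthetic landscape

The generator emulates the features the estimators must recover:
spatially autocorrelated drivers (Gaussian-smoothed white noise,
correlation length 8 cells by default, standardized), a
distance-to-city layer, a spatially coherent initial map laid out by
quantiles of a smooth field with a construction seed patch, and
transitions drawn without replacement with probability proportional to
`plogis(intercept + coefs · drivers)` subject to a per-step demand —
which makes the generator demand-exact while preserving the monotone
link between true probability and conversion frequency (tested by
binning). Default demands scale with the grid (4% of cells to
construction, 2% to forests per step); logit coefficients of magnitude
1–2.5 give development signals comparable to strongly driven real
landscapes. The exact per-cell probabilities are returned, enabling
rank-correlation and discrimination checks of the fitted surfaces
against truth.

What the generator does *not* emulate: real driver collinearity,
class-specific patch-shape geometry, multi-scale policy zoning, or
measurement error in the input maps. Passing tests therefore show the
estimators recover logistic-in-drivers expansion with autocorrelated
fields — not that any particular real basin is simulated accurately;
accuracy on real data must be established with the validation metrics
against held-out dates.

## Problem sizes and numerical choices

The test suite exercises 100×100 landscapes for the shared fixtures,
a 200×200 landscape for the allocation audit, 20-seed replicate sets
at 80×80 for expansion-probability recovery, and 20 seeded
figure-of-merit comparisons against random allocation — sizes chosen
so the full suite runs in well under a minute of compute per heavy
block while leaving each property statistically meaningful. Ties in
the roulette draw are resolved by the first cumulative bin; grids are
row-major with cell centers at half-offsets; buffer distances are
cell-center Euclidean. Degenerate inputs (all-nodata rasters,
single-class confusion matrices, both-zero growth rates, collinear
point sets, non-positive gray-model series) all have explicit, tested
error or NA paths rather than silent results.
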