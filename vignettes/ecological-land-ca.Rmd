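---
title: "Scenario simulation of ecological-land change with a constrained CA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scenario simulation of ecological-land change with a constrained CA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecolandca)
```

## The modeling problem

Regional ecological land — forest, grassland, wetland — erodes under
urbanization and cropland reclamation. The question this package answers is
spatial: *where* will land-use change fall under a given policy regime, and
how well does each regime protect ecological land? The approach is the
classic two-level scenario CA: a **macro controller** fixes how much area
each class should reach, and a **micro engine** decides which cells deliver
that change.

The three scenarios differ in both targets and constraints:

| scenario | macro targets | inviolable cells |
|---|---|---|
| natural development | Markov trend projection | basic farmland |
| object orientation | planning caps | basic farmland, water |
| ecosystem priority | planning caps, stricter cropland return | core protection areas; no construction above 25° slope; no loss of any ecological cell |

## Model components and assumptions

### Markov macro prediction

`crosstab()` tallies the inter-class transition matrix between two observed
maps; `to_probability()` row-normalizes it. The Markov assumption —
transition probabilities stationary over five-year monitoring steps — is
used only to set *area demands*, never cell locations. The estimated
one-step matrix is treated as a five-year step; projecting a fifteen-year
horizon uses `steps = 3`. By algebraic identity, one projection step
through the estimated matrix reproduces the second epoch's areas exactly;
the test suite asserts this on arbitrary map pairs.

A class absent at the first epoch keeps an identity row rather than NaNs so
toy inputs degrade gracefully.

### Suitability regressions and Theil normalization

Conversion suitability is fitted by three separate binary logistic
regressions (maximum likelihood, `stats::glm`, deviance tolerance 1e-8):
"converted to class m between the epochs" on the seven drivers, over cells
*eligible* to convert (not already in class m). Separate binary fits mirror
the calibration protocol of the method; the per-cell probabilities are then
made coherent by ratio (Theil) normalization, which preserves the per-cell
argmax. Cells where every class probability is zero are flagged and given
the uniform distribution.

Two design choices deserve emphasis:

* **Sampling frame.** The calibration sample excludes constraint-masked
  cells (`exclude` argument): statutorily protected cells are structural
  non-converters and would attenuate every coefficient toward zero if
  treated as free observations.
* **No model for "other" land.** Only three conversion outcomes are
  modeled (cultivated, ecological, construction); bare/unused land has no
  suitability surface, so the engine never converts cells *into* it. That
  matches its monotone decline in all scenarios; a landscape where "other"
  must grow is outside this model's scope.

### The synthesis probability and conversion rule

Per candidate cell and class, `P_T = P_global × Ω × con × R`:

* `Ω` is the 3×3 Moore-neighborhood share with an edge-aware denominator
  (interior 8, edges 5, corners 3), promoting compact growth.
* `con` is 0/1 from the scenario's constraint recipe. Under ecosystem
  priority the ecological protection is *dynamic*: any cell currently
  ecological (including cells gained during the run) may not convert out.
* `R = 1 + (−ln γ)^α`, one fresh `γ` per cell per iteration. The printed
  source for this disturbance term is an unreadable figure; the
  implemented form is the standard stochastic perturbation of CA land-use
  models and should be read as a reconstruction. `α = 1` by default: the
  disturbance then has mean 2 and an exponential tail, enough to randomize
  marginal candidates without drowning the suitability signal; larger `α`
  makes the tail — and the randomness — heavier.

Each iteration min–max normalizes `P_T` over that iteration's candidate
cells (constrained zeros are excluded so they cannot pin the minimum) and
converts the cells at or above the threshold `P_threshold`, best first.
The threshold is a required scenario parameter with default 0.8. The
comparison direction is `">="`; the literal published rule ("convert when
`P_T < P_threshold`") is available as `threshold_direction = "lt"` but
inverts suitability — high-suitability cells would never develop — so it is
not the default.

### Demand steering and the stopping band

The published stopping rule halts iteration for a class once its cell count
enters `(X_target − N, X_target + N)`. Implemented literally as a *freeze
at band entry*, this deadlocks: gaps across classes sum to zero, so after
three classes freeze just inside their band edges the fourth can be
stranded outside its band with no partner left to trade with (observed on
the default synthetic landscape). The engine therefore separates two roles:

* **allocation** steers every class toward its *exact* target — a class
  accepts conversions only while below target (capped by its remaining
  demand) and releases cells only while above it (per-source release
  budgets). Every conversion moves both classes involved strictly toward
  their targets, so total imbalance decreases monotonically and the run
  cannot cycle;
* **stopping** uses the closed band `[X_target − N, X_target + N]`: the
  run ends when every class is inside it (or at `max_iter`, reported per
  class, never thrown).

`N` defaults to `max(1% of the class target, 0.1% of the landscape)`. The
floor keeps the band wider than the allocation granularity for tiny
classes — "other" occupies ~0.2% of the landscape and cannot gain cells,
so a band of a few cells would report spurious non-convergence.

With the 0.8 threshold, one sweep converts roughly the top
`candidates^0.2` cells (the extreme disturbance draw sets the
normalization maximum), so realistic demands take on the order of a
thousand sweeps; `max_iter` defaults to 3000 and the engine maintains
neighborhood counts incrementally so a sweep is cheap. Determinism: ties in
the conversion ranking break by row-major cell order; with the seed fixed,
runs are bit-reproducible (asserted in the tests).

Construction is absorbing during simulation: all scenarios here have
non-decreasing construction demand, and allowing demolition would require a
suitability model for it.

### Landscape metrics

Patch labeling uses 8-connectivity and AI uses single-counted 4-neighbor
like adjacencies with the combinatorial `max_g` bound — the Fragstats
conventions, since that is the de-facto metric engine of this literature.
Perimeters count cell edges adjacent to another class, nodata, or the
boundary. A single-cell class has no possible like adjacency; AI returns
100 by convention with a `degenerate` flag. All four indices are verified
against independent brute-force implementations (naive label propagation
and double-loop counts) to 1e-9 on random grids.

## The synthetic landscape generator

The generator emulates the statistical structure the calibration assumes,
with known truth:

* **Drivers.** Distance transforms from seeded towns and random-walk
  river/highway polylines; a box-smoothed uniform DEM (width 11) and its
  gradient-magnitude slope; IDW (power 2, all points contributing)
  socio-economic fields, population concentrated near towns. Every layer
  is standardized to (0, 1) by quantile (rank) normalization: uniform
  marginals give each driver full contrast on the standardized range.
  A plain min–max map on smooth fields concentrates mass mid-range
  (marginal sd ≈ 0.1–0.25), which roughly doubles coefficient standard
  errors and would make truth recovery — the generator's purpose — fail at
  noise level.
* **Initial map.** Greedy score-based allocation (construction near towns
  and dense population, ecological on high/steep terrain, cultivated on
  flat low ground, smoothed noise for patchiness) hits the spec shares
  exactly up to rounding. Defaults mirror the published 2005 status:
  shares (25, 56, 18, 1)%, 300×300 cells of 100 m.
* **True conversion process.** Cell `i` converts to class `m` with
  probability `intensity_m × plogis(β*_m · x_i)`; a single uniform draw
  allocates among competing classes, which gives exact logistic marginals
  whenever the class probabilities sum to at most one (violations are
  rescaled and counted; zero on the default landscape). The slope vectors
  `β*` are fixed, interpretable, and all of magnitude ≥ 1.2 — exact-zero
  effects are not a realistic feature of these drivers. The intercepts are
  *derived*, calibrated by `uniroot` so the expected fraction of eligible
  cells converting into each class matches the published 2000–2005 gross
  conversion intensities (10.3% cultivated, 11.3% ecological, 8.6%
  construction). Masked core-area cells never convert.
* **Masks.** Basic farmland = flattest 30% of cultivated cells; water =
  4% of ecological/other nearest rivers; reserves = highest 10% of
  ecological; steep slope = top 5% of the slope layer; key-ecological
  security levels split ecological cells by proximity to towns (15% low,
  35% high security). Order-based selection makes fractions exact up to
  one cell.
* **Scenario caps.** The synthetic planning caps mirror the stringency of
  the published planning constraints relative to trend: construction
  increment capped at 32% of the Markov-projected increment, cultivated
  decline capped at 5.5% (object orientation) and 8% (ecosystem priority,
  where more farmland returns to forest).

What the generator does **not** emulate: real geography (road networks,
contiguous administrative zoning), multi-date socio-economic trajectories,
class-imbalanced subclass structure, or spatially correlated residuals
beyond what the smooth drivers induce. Passing tests therefore demonstrate
that the estimators and the engine are correct and internally consistent
under the stated generating process — not that the model is adequate for
any particular real region.

## Problem sizes and numerical conventions

The test suite and the acceptance script use the default 300×300 landscape
(90,000 cells; ≈76,000 eligible calibration rows after mask exclusion) for
calibration recovery, hold-out validation and the three-scenario
comparison, and an 80×80 landscape for engine-invariant stress tests
(1,000+ seeded iterations). Recovery of each driver coefficient is asserted
within ±15% relative (±0.05 absolute near zero); intercepts are excluded
from that check — they are derived calibration anchors, and a near-zero
intercept cannot beat its own sampling error at this design size — and are
covered instead by the maximum-likelihood balance property (mean fitted
probability equals the observed conversion rate). Areas are computed in
full precision and rounded only for display (2 decimals, matching the
precision of the published tables). One top-level seed fans out to fixed
per-stage seeds, so a single integer reproduces the entire pipeline.

## Known limitations

* Time enters only through abstract iteration sweeps controlled by the
  stopping band; there is no sub-interval calendar.
* The Markov demand model is stationary; regime shifts between calibration
  and target epochs must be expressed through planning caps.
* Constraints are binary. Graded friction surfaces (`con ∈ (0, 1)`) are
  accepted by `synthesis_probability()` but no scenario recipe produces
  them.
* Single-CPU, in-memory lattices; practical up to a few million cells.
* Vector/irregular cellular spaces and multi-agent decision layers are out
  of scope.
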