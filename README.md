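# ecolandca

Constrained cellular-automaton (CA) simulation of regional ecological-land
change under alternative protection policies.

Rapidly urbanizing regions convert forest, grassland and wetland —
*ecological land* — into construction and cropland. Planners need spatially
explicit forecasts of where that conversion will happen under different
policy regimes: unconstrained continuation of the current trend, planning
caps on construction growth and cropland loss, or strict priority for
ecosystem protection. `ecolandca` implements the standard scenario-CA
toolchain for this question and is aimed at landscape ecologists and
land-system modelers working with categorical land-use rasters
(four classes: cultivated, ecological, construction, other; 100 m cells by
default).

## The model

The simulator couples a macro area controller with micro-scale cell
transition rules.

**Macro prediction.** Inter-class transitions between two observed epochs
are cross-tabulated into a transition matrix; its row-normalized Markov
form `P_ij` projects class areas forward, `X_{t+1} = X_t P`. Policy
scenarios replace the trend projection with planning caps (maximum
construction increment, maximum cultivated decline; the
ecological + other balance absorbs the remainder). The CA iterates until
every class's cell count lies in the closed stopping band
`[X_target − N, X_target + N]`.

**Micro evolution.** For each cell `i` and candidate class `m`, the
synthesis conversion probability is the product

```
P_T(i,m) = P(i_m) × Ω(i_m) × con(i) × R
```

where

* `P(i_m)` — global suitability from a binary logistic regression of
  observed conversions on seven normalized drivers (distances to town,
  highway and river, DEM, slope, per-capita GDP, population density),
  with the separately fitted class probabilities made coherent per cell by
  Theil (ratio) normalization, `P'(i_j) = P(i_j) / Σ_k P(i_k)`;
* `Ω(i_m)` — the Moore-neighborhood share of class `m` (3×3 window,
  center excluded);
* `con(i)` — scenario constraint masks (basic farmland, water, core
  protection areas, slopes above 25°, all-ecological protection), 0 =
  conversion prohibited;
* `R = 1 + (−ln γ)^α` — a stochastic disturbance with `γ ~ U(0,1)` and
  integer `α ∈ 1..10`.

Per iteration, `P_T` is min–max normalized over the candidate cells and
compared with a threshold (default 0.8); passing cells convert, highest
probability first, capped by the remaining class demand.

**Evaluation.** Class-level landscape pattern metrics in the Fragstats
conventions — largest patch index (LPI), patch cohesion (COHESION),
splitting index (SPLIT), aggregation index (AI) — plus per-class area
change accounting, cell-by-cell overlay accuracy, and the loss of
security-flagged key ecological land.

A seeded synthetic-landscape generator (`synth_spec()`, `synth_bundle()`)
produces aligned two-epoch maps, drivers, and constraint masks from a known
logistic conversion process, so calibration, simulation and evaluation are
all testable against ground truth without any proprietary rasters.

## Worked example

Desk-scale accounting from the published Beijing 2000–2005 transition
matrix shipped with the package:

```r
library(ecolandca)
bj <- beijing_tables()
round(to_probability(bj$transition)["cultivated", ], 4)
#>   cultivated   ecological construction        other
#>       0.6614       0.1359       0.2008       0.0019
```

So a cultivated cell had a 20.1% probability of becoming construction land
within the five-year interval. Scenario accounting against the 2005 status:

```r
base <- setNames(bj$areas$status_2005, bj$areas$class)
nd   <- setNames(bj$areas$natural_development, bj$areas$class)
area_change_summary(base, nd)
#>          class base_km2 result_km2 change_km2 change_pct
#> 1   cultivated  4232.66    3798.57    -434.09 -10.255726
#> 2   ecological  9237.15    8728.13    -509.02  -5.510574
#> 3 construction  2885.32    3835.82     950.50  32.942620
#> 4        other    30.59      23.20      -7.39 -24.158222
```

Under trend continuation, construction grows by 32.9% while ecological land
loses 509 km². A full synthetic pipeline — generate a landscape, calibrate,
simulate the three scenarios:

```r
spec   <- synth_spec(shape = c(120, 120), seed = 7)
bundle <- synth_bundle(spec)
cal    <- eca_calibrate(bundle$map_t0, bundle$map_t1, bundle$drivers,
                        fraction = 1, seed = 7,
                        exclude = bundle$masks$core_area)
targets <- scenario_targets(area_table(bundle$map_t1), cal$transition,
                            steps = 3)
report  <- run_all_scenarios(bundle$map_t1, bundle$drivers, bundle$masks,
                             cal, targets, seed = 7)
report
#> Scenario comparison report (seed 7 )
#>
#> Final ecological-land area (km^2):
#> natural_development  object_orientation  ecosystem_priority
#>               71.15               78.34               79.01
#>
#> Ecological-land pattern metrics:
#>                        lpi cohesion  split     ai
#> status              27.160   98.610  8.566 75.680
#> natural_development 23.410   98.519 10.958 78.672
#> object_orientation  27.528   98.603  8.311 77.017
#> ecosystem_priority  27.764   98.588  8.183 77.791
#>
#> Key-ecological-land loss (km^2):
#>                      low high
#> natural_development 1.11 1.27
#> object_orientation  0.00 0.00
#> ecosystem_priority  0.00 0.00
```

Ecological land fares best under ecosystem priority and worst under natural
development — in final area, in the dominance and cohesion of its patches
(higher LPI, lower SPLIT), and in key-land losses — reproducing the
qualitative scenario ranking the method was designed to demonstrate.

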