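---
title: "Methods: spatial coupling of population aging and elderly-care resources"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial coupling of population aging and elderly-care resources}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agecouple)
```

## The problem

Where an older-adult population concentrates and where elderly-care
resources are supplied rarely coincide. `agecouple` quantifies that
supply–demand relationship at the city scale for a region partitioned into
contiguous administrative units. The demand side is the older-adult (65+)
population; the supply side is four resource classes, each expressed per
10,000 older adults: care facilities (life services), park green space
(ecological environment), basic old-age-insurance participants (social
security), and medical beds (medical and health). The pipeline answers
three questions in sequence: where is aging concentrated (staging,
agglomeration, hot spots); how closely do the two systems co-vary overall
(grey relational coupling); and how well does each individual resource
match demand city by city (coupling-coordination matching).

## Demand-side metrics

The **aging coefficient** `W = 100 * pop_65plus / pop_total` (percent)
stages a population as young (`W <= 4`), adult (`4 < W < 7`), primary
(`7 <= W < 14`), moderate (`14 <= W < 21`), or severe (`W >= 21`). The
boundary conventions are exactly the inequalities conventional in the
demographic-staging literature;
because census inputs are integers, a ratio can land exactly on a
boundary, so classification snaps values within `1e-12` of a threshold
onto it before comparing — floating error cannot push a city across a
stage boundary.

The **dependence rate** `X2 = 100 * pop_65plus / pop_15_64` measures
older adults per 100 working-age persons.

The **agglomeration degree** `JJD = (P_i / A_i) / (P_n / A_n)` compares a
city's older-adult density with the national density; over any partition
of the nation the area-weighted mean is exactly 1, which the test suite
verifies to `1e-9` as a cross-module identity. Density classes use
left-open/right-closed intervals at 3, 6, 9, 12.

## Hot and cold spots

Contiguity weights are binary and symmetric (queen rule by default: any
shared boundary point). The local Getis–Ord statistic is the
neighbourhood share `(sum_j w_ij x_j) / (sum_j x_j)`. Two variants exist
because one common printed form of the statistic excludes the self term
from the denominator while the canonical Gi* includes the unit in its own
neighbourhood; the
package defaults to the canonical self-inclusive form (`include_self =
TRUE`, standard GIS semantics) and offers the literal self-exclusive form
via `gi_variant = "literal"`.

`gi_star_z()` standardizes with the standard Ord–Getis randomization
moments:

    z_i = [sum_j w_ij x_j - xbar * W_i] / (S * sqrt((n * S1_i - W_i^2) / (n - 1)))

with `W_i` the weight sum, `S1_i = W_i` for binary weights, and `xbar`,
`S` the mean and population standard deviation over all units. A surface
that is constant (up to a relative variance of `1e-12`, so quantization
residue does not masquerade as signal) yields all-zero z with a warning
rather than an error, keeping degenerate synthetic fixtures running.

As a model-free check, `permutation_test()` provides conditional
permutation inference: unit i's value is held fixed, the remaining values
are reassigned at random, and the pseudo p-value is the folded two-sided
rank `(min(n_ge, n_le) + 1) / (n_perm + 1)`. One structural property of
this null is worth knowing: a *single* extreme cell can never be
significant at its neighbours, because the spike re-enters their
conditional nulls through resampling; only clustered elevation is
detectable, which is precisely what a *local* clustering statistic is
for. Pattern labels (cold, sub_cold, sub_hot, hot) come from four-class
natural breaks on z — the statistic itself is classed, as is common in
applied hotspot mapping; fixed ±1.65 cutoffs are available as an
alternative.

## Normalization and natural breaks

All indicators are positive-oriented; range (min–max) normalization maps
each column onto `[0, 1]` and is idempotent and invariant to positive
affine transforms. Constant columns raise an error by default
(configurable to emit 0.5).

`jenks_breaks()` implements the exact Fisher optimal-partition dynamic
program — not the common reinitialized k-means heuristic — so the
classification minimizing within-class sum of squared deviations is
deterministic and can be checked against exhaustive enumeration (the test
suite does exactly that for all n ≤ 12, k ≤ 4 over hundreds of random
instances). Ties are broken toward the lowest-index break. Intervals are
left-open/right-closed, the way class bounds are conventionally reported
(`a < v <= b`), with the lowest interval closed at the data minimum. A goodness-of-variance fit is reported for diagnostics.

## Grey relational coupling

Demand (X1, X2) and supply (Y1–Y4) are range-normalized, then for every
demand indicator i, supply indicator j and city c:

    R_ijc = (dmin + rho * dmax) / (|Xn_ci - Yn_cj| + rho * dmax)

with `dmin`/`dmax` global over all i, j, c and distinguishing rate
`rho = 0.5` by default. Grey relational analysis is usually presented
with a time index, but this analysis is a single cross-section; the sample index is therefore the
city, and `k` in the relation grade `gamma_ij = mean_c R_ijc` is the
number of cities. The system coupling degree `C` is the grand mean of
`gamma` — equivalently the grand mean of R — so `mean(d_demand) =
mean(d_supply) = C` holds to machine precision and is asserted in tests.
A per-city coupling degree (the mean of R over indicator pairs for that
city) supports city-level coupling maps; it is the only reading under
which such a map exists. Categories use left-open/right-closed intervals
at 0.35, 0.65, 0.85.

Two formula consequences are documented rather than "fixed": when
`dmin = 0` every coefficient is bounded below by `rho / (1 + rho)` (1/3
at the default), so the prose claim that grades span (0, 1) is not
attainable from the formula; and identical normalized systems make the
ratio 0/0, which is resolved to R = 1 everywhere with an informational
message (perfect coupling, not an error). Larger `rho` compresses
differences less, and C is monotone non-decreasing in `rho` for fixed
data (property-tested).

## Coupling-coordination matching

The per-resource matching statistic is the two-system coupling degree

    C(x, y) = 2 * sqrt(x * y) / (x + y)

between the normalized aging level x and one normalized resource level y
— the standard two-system coupling degree, the only form consistent
with `C` in `[0, 1]`, symmetry, and a maximum at `x = y`.
Raw scales (an aging share near 15 against beds near 300) would pin C
near 0 everywhere, so both sides are min–max normalized across cities
first (`normalize = FALSE` exists for pre-normalized input).

Min–max normalization always produces one city with `x = 0`, so the
convention at `(0, 0)` decides whether perfectly proportional supply can
ever be uniformly matched. The package defines `C(0, 0) = 1`: zero
supply for zero demand is a balanced pair, `C(x, x) = 1` then holds
without exception, and the exact-proportionality limit (`beta = 1`,
`sigma = 0` in the generator) yields `C = 1` for every city, as it
should. `C(0, y) = 0` for `y > 0` is unchanged — one-sided vanishing is
the worst mismatch. The function has no limit at the origin, so any
convention is discontinuous; this one makes "matched" mean `x = y`
everywhere.

Coordination values are carried at four decimal places (the reporting
precision used for coupling quantities throughout), and matching classes
are fit per resource column — severe_mismatch through high_match by
five-class natural breaks on the rounded values. When fewer distinct
values than classes remain (e.g. all cities exactly matched), the column
falls back to as many classes as there are distinct values, labelled by
the position of each class mean on the absolute `[0, 1]` scale: an all-1
column is uniformly high_match, an all-0.02 column uniformly
severe_mismatch. Natural-breaks labels are otherwise *relative* within
the study region; they rank cities against each other, not against an
absolute adequacy standard.

## The synthetic-region generator

Real census and yearbook city tables are not redistributable, so
`generate_region()` builds study regions with the statistical structure
the analysis assumes, and the defaults are fixed once to emulate a
Yangtze-Delta-like study region:

* **Geometry**: a 6 × 7 grid of cells, nominal area 8,700 km² each
  (≈ 360,000 km² over 41 units); `default_yrd_like()` removes one corner
  cell — the one with the most median aging share, so the field extremes
  survive — leaving 41 contiguous cities. Queen contiguity by default.
* **Population**: log-normal density, `log(400)` mean and 0.8 log-sd —
  median cities of a few million with a heavy upper tail, as in real
  city systems.
* **Aging field**: a standard-normal innovation per cell, smoothed by 3
  neighbour-averaging passes (spatial autocorrelation strong enough that
  ≥ 90% of seeds produce at least one |z| > 1.65 hotspot, verified over
  50 seeds), then rescaled to span exactly `15 ± 6.5` percent. The span
  guarantees every seed realizes primary, moderate and severe stages with
  a moderate-stage majority, the mix characteristic of rapidly aging
  regions.
* **Working-age population**: 82% of the non-elderly population, a
  typical share once children are removed.
* **Resources**: per-10,000-older-adults level `base_j * ((1 - beta_j) +
  beta_j * X1_norm + sigma_j * noise)`, truncated at zero, with base
  levels (1.2 facilities, 200 ha green space, 2,800 insured, 320 beds)
  matching per-capita magnitudes seen in city statistical yearbooks,
  `beta = 0.7` and `sigma = 0.15` by default — supply that tracks demand
  imperfectly, the situation the method exists to diagnose.
* **Quantization**: populations and resource quantities are rounded to
  integers by default (census tables are counts). `integer_counts =
  FALSE` keeps all quantities continuous; the closed-form limits (exact
  proportionality, perfectly flat aging surfaces) exist only there,
  because rounding is itself a small noise source. Tests of those limits
  use the continuous mode; everything stochastic runs on integer data.

What the generator does **not** emulate: real administrative geography
(areas are equal up to optional jitter), correlation between city size
and resource endowment beyond what `beta` induces, multiple time points,
and within-city heterogeneity. Passing tests therefore demonstrate the
correctness and calibration of the *methods*, not empirical claims about
any real region.

Seeds are mandatory throughout — there is no hidden global RNG state, and
the caller's RNG state is restored after every draw.

## Numerical conventions

* Threshold classification snaps to boundaries within `1e-12` before
  comparing.
* Percent shares round half away from zero to two decimals (12 of 41
  cities prints 29.27, 2 of 41 prints 4.88).
* The Gi* z-score treats relative variance below `1e-12` as constant.
* Natural-breaks ties resolve toward the lowest-index break.
* The Jenks dynamic program is exact; its cost is O(k·n²), trivial at
  city-system sizes.

## Problem sizes used for verification

The test suite runs the permutation-agreement experiment on 5 × 5 grids
with 9,999 conditional permutations over 100 trials (analytic |z| > 2.5
implies permutation p < 0.05 in ≥ 95% of flagged units); the
noise-monotonicity and mismatch-count experiments average 20 seeds per
noise level on the 41-city default region; Jenks is checked against
exhaustive enumeration for n ≤ 12, k ≤ 4 over 500 random instances.
These sizes were chosen so each property is measured with comfortable
statistical margin at interactive runtimes.

## Limitations

* Contiguity is the only supported weight structure (the method under
  study uses it exclusively); no distance-band or kernel weights.
* The coupling-coordination analysis stops at the coupling degree C; the
  common coordination-degree extension `D = sqrt(C * T)` with a weighted
  development index is out of scope.
* Natural-breaks class bounds are data-relative: bounds fitted on one
  region do not transfer to another.
* Geometry handling is deliberately minimal (GeoJSON polygons, shared
  vertices for contiguity); there is no reprojection, and polygon
  contiguity assumes shared borders repeat vertices exactly, as the
  package's own writer guarantees.

## A minimal run

```{r example}
region <- default_yrd_like(seed = 1)
profile <- aging_profile(region)
table(profile$stage)

ind <- build_indicators(region)
coupling <- grey_coupling(ind, rho = 0.5)
round(coupling$C, 4)

matching <- match_resources(ind)
sapply(matching$match_class, function(cl) sum(cl == "high_match"))
```
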