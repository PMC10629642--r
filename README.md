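# agecouple

Spatial supply–demand coupling between an aging population and
elderly-care resources, at the city scale.

Regional planners and health-services researchers face a recurring
question: do the places where older adults concentrate also hold the
care resources they need? `agecouple` implements a complete analysis
chain for a region partitioned into contiguous city units, with the
older-adult (65+) population as the demand system and four resource
classes — care facilities, park green space, old-age-insurance
participants, and medical beds, each per 10,000 older adults — as the
supply system.

## What it computes

**Demand-side structure.** The aging coefficient
`W = 100·P65/P` with the five-stage classification (young ≤ 4 < adult
< 7 ≤ primary < 14 ≤ moderate < 21 ≤ severe), the old-age dependence
rate `X2 = 100·P65/P15–64`, and the agglomeration degree

    JJD_i = (P_i / A_i) / (P_n / A_n)

— the city's older-adult density relative to the national density, with
five density classes (sparse ≤ 3 < low ≤ 6 < medium ≤ 9 < high ≤ 12 <
super-high).

**Hot/cold spots.** Getis–Ord Gi\* on binary contiguity weights
(queen or rook), standardized with the Ord–Getis randomization moments

    z_i = [Σ_j w_ij x_j − x̄ W_i] / (S √((n S1_i − W_i²)/(n − 1)))

plus conditional-permutation pseudo p-values as a model-free check, and
four-class natural-breaks pattern labels (cold … hot).

**Grey relational coupling.** With demand and supply indicators
range-normalized across cities, relation coefficients

    R_ijc = (Δmin + ρ·Δmax) / (Δ_ijc + ρ·Δmax),  Δ_ijc = |Xn_ci − Yn_cj|

with distinguishing rate ρ = 0.5 by default; relation grades
`γ_ij = mean_c R_ijc`; indicator-mean grades; and the system coupling
degree `C = mean(γ)`, classified as low/moderate/relatively-high/high at
0.35, 0.65, 0.85.

**Coupling-coordination matching.** Per city and per resource,

    C(x, y) = 2√(x·y) / (x + y)

between normalized demand and supply, with five natural-breaks matching
classes from severe mismatch to high match.

**Shared machinery.** Exact Fisher–Jenks natural breaks (dynamic
programming, deterministic, oracle-checkable), range normalization,
class-share reporting with half-up percentage rounding, and a
synthetic-region generator that produces contiguous grid "nations" with
spatially autocorrelated aging and tunably coupled resources, so the
whole pipeline is testable without restricted census data.

## Worked example

```r
library(agecouple)

region  <- default_yrd_like(seed = 1)   # 41 contiguous synthetic cities
profile <- aging_profile(region)
table(profile$stage)
#>    young    adult  primary moderate   severe
#>        0        0       14       22        5

ind      <- build_indicators(region)    # X1, X2, Y1..Y4 per city
coupling <- grey_coupling(ind, rho = 0.5)
round(coupling$C, 4)
#> [1] 0.673
round(coupling$d_supply, 4)
#>     Y1     Y2     Y3     Y4
#> 0.6358 0.6930 0.6821 0.6810

matching <- match_resources(ind)
sapply(matching$match_class, function(cl) sum(cl == "high_match"))
#> Y1 Y2 Y3 Y4
#> 19 27 19 24
```

Reading the output: of the 41 synthetic cities, 14 are in the primary
aging stage, 22 moderate and 5 severe (34.15%, 53.66% and 12.20% via
`class_shares()`). The system coupling degree 0.673 falls in the
relatively-high band — supply broadly tracks demand — with social
security (Y3) and green space (Y2) coupling slightly more strongly than
facilities (Y1). The matching counts say how many cities reach the
highest coordination class for each resource.

The hotspot stage works the same way:

```r
w  <- contiguity_weights(region)        # queen contiguity, self-inclusive
hs <- hotspot_analysis(profile$W, w)
table(hs$pattern_class)
#>     cold sub_cold  sub_hot      hot
#>       11       13        9        8
```

A full run — ingest or synthesize, indicators, aging profile, hotspots,
resource classes, grey coupling, matching, CSV/JSON/GeoJSON artifacts —
is one call:

```r
bundle <- run_pipeline(pipeline_config(seed = 1, out_dir = "results"))
```

and a thin command-line front end covers each stage
(`inst/cli/agecouple.R run|synth|aging|hotspot|classify|grey-coupling|match`).

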