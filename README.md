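# geoimpute

Demographically weighted geoimputation and positional-error evaluation.

## The problem

Spatial epidemiology needs point-level locations, but health and
administrative records are routinely available only at a coarse census unit
(block group, tract, county) — for privacy, or because the address was never
geocoded. **Geoimputation** assigns each such record a finer coordinate
using ancillary data: here, block-level population counts by sex, race and
age range (the decennial-census style tabulation, 2 × 9 × 23 = 414
categories).

`geoimpute` is for methodologists and analysts who want to (a) impute
coordinates for coarsely located records and (b) quantify, on data with
known truth, how accurate each strategy is and for whom.

## The strategies

For a record with demographic category *c* in coarse unit *u*, each member
block *b* has weight

```
w(b, c) = count(b, c) / Σ_{b' ∈ u} count(b', c)
```

its share of the unit's population in that category. The four strategies:

| id | method | type |
|----|--------|------|
| S1 | uniform random point in the whole unit | stochastic |
| S2 | uniform random point over the union of blocks with w > 0 | stochastic |
| S3 | centroid of the block with maximal w (ties: lowest block id) | deterministic |
| S4 | weighted mean of block centroids, Σ w(b,c)·centroid(b) | deterministic |

S3/S4 are *unimputable* for records whose category has no population
anywhere in the unit; S1 always succeeds, S2 falls back to S1 and flags it.

Accuracy is measured by the **error distance**: the planar Euclidean
distance in meters between a record's true coordinate and the imputed one,
after deliberately coarsening records with known locations. The evaluation
framework stratifies errors by strategy, race, sex, age group and
population-density decade, validates stochastic strategies by multiple
imputation, repeats the analysis at tract and county coarsening, aggregates
worst-case errors per tract, and interpolates error surfaces by inverse
distance weighting.

A synthetic census generator (nested rectangular block/group/tract/county
hierarchy, Dirichlet-controlled racial clustering, configurable
population-density gradient, exact population conservation) makes the whole
pipeline testable without restricted-access data.

## Worked example

```r
library(geoimpute)

# a census-like world: 100 block groups x 16 blocks, 200k people,
# minorities spatially clustered; 5,000 records with known coordinates
sc <- generate_scenario("clustered_minorities", seed = 1)
sc$geography
#> <census_geography> 1600 blocks, 100 block groups, 25 tracts, 9 counties; population 200000

# records are already coarsened to their block group; impute with all four
# strategies, 10 replicates for the stochastic ones
imp <- impute_batch(sc$records, sc$geography, n_replicates = 10, seed = 2)
err <- evaluate_errors(imp, sc$records, sc$geography)
s <- stratified_summary(err, "strategy")
print(s[, c("strategy", "n", "mean_m", "median_m", "q1_m", "q3_m", "se_m")],
      digits = 4)
#>   strategy     n mean_m median_m   q1_m q3_m   se_m
#> 1       S1 50000   1674     1646 1050.6 2266  3.561
#> 2       S2 50000   1435     1382  658.3 2092  3.863
#> 3       S3  5000   1177     1002  363.0 1884 12.680
#> 4       S4  5000   1022     1013  623.0 1384  7.183
```

The weighted mean method (S4) recovers locations with the lowest mean error,
followed by the maximum-weight centroid (S3), the random point in matching
blocks (S2) and the unrestricted random point (S1): demographic information
buys roughly a third of the baseline error in this clustered condition.
Stochastic strategies have 10 rows per record (50,000 = 5,000 × 10);
deterministic ones a single row.

Other entry points: `density_bins()` (accuracy by population-density
decade), `multiple_imputation_summary()` (replicate stability),
`sensitivity_by_level()` (block group vs tract vs county coarsening),
`tract_accuracy_aggregation()` and `idw_interpolate()` (error surfaces),
`make_unmatchable()` (records no demographic strategy can place),
`run_pipeline()` and `inst/cli/geoimpute.R` (file-based end-to-end runs).
See `vignette("geoimputation-methods")` for the model and design choices.

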