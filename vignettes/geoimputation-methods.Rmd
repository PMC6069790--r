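---
title: "Geoimputation methods: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geoimputation methods: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geoimpute)
```

## The problem

Health and administrative records often carry only a coarse location — a
census block group, tract, county or ZIP code — either because the address
was never geocoded or because privacy rules require aggregation.
*Geoimputation* assigns each such record a finer-resolution coordinate using
ancillary data, here block-level demographic counts: if a 71-year-old white
female is known only to live somewhere in a block group, the blocks of that
group that actually contain white females aged 70–74 are better guesses than
the group at large.

`geoimpute` implements four strategies and, equally importantly, the
framework to evaluate them: records with *known* coordinates are artificially
coarsened to their containing unit, re-imputed, and scored by the planar
Euclidean distance between the true and imputed points (the *error
distance*, in meters).

## The demographic weight

All demographic information enters through one quantity. For a record with
demographic category $c$ (a sex × race × age-bin cell) in coarse unit $u$,
the weight of member block $b$ is

$$w_{b,c} \;=\; \frac{n_{b,c}}{\sum_{b' \in u} n_{b',c}},$$

the block's share of the unit's population in that category. Weights over a
unit sum to 1 whenever the denominator is positive. A zero denominator means
*no matching population anywhere in the unit*: this is returned as a
value-level no-match signal (`NA`), not an error, because the strategies
must count such records as unimputable rather than crash — in real data a
few percent of records fall in this class (stale addresses relative to the
census date, race misclassification).

The default category space mirrors decennial-census block tabulations:
2 sexes × 9 race/ethnicity groups × 23 age ranges = 414 categories. Indices
are 1-based and sex-major (sex, then race, then age bin), so a category
addresses a column of the per-block counts matrix directly. Registry race
codings rarely match census groups; `map_race_labels()` takes a
user-supplied correspondence table rather than hard-coding one, since the
right mapping (e.g. whether "white, unknown ethnicity" is White or Hispanic)
is a study-level decision.

## The four strategies

* **S1 — random point in the coarse unit** (stochastic). Uniform over the
  unit's area. The demographic-free baseline.
* **S2 — random point in matching blocks** (stochastic). Uniform over the
  union of member blocks with $n_{b,c} > 0$, implemented as: choose a
  matching block with probability proportional to its *area*, then uniform
  inside it. The field describes this strategy only as "random within the
  matching blocks' extents"; area-proportional choice is the unique law that
  makes the point uniform over the union, so it is the default. A
  population-weighted block choice is available via
  `impute_batch(..., s2_weighting = "population")` but off by default, to
  keep S2 a purely spatial randomiser in contrast to S3/S4. When *no* block
  matches, S2 falls back to S1 behaviour and sets `fallback_used = TRUE`:
  the record stays imputed (so stochastic strategies always return a point)
  but the fallback is auditable, letting users reproduce either accounting
  convention.
* **S3 — maximum-weight centroid** (deterministic). The centroid of the
  block with the largest $w_{b,c}$; ties broken by ascending block id
  (determinism is required for reproducibility; the choice among ties is
  otherwise arbitrary). Every record of a given (unit, category) maps to the
  same point, so S3 is prone to *artificial clustering*.
* **S4 — weighted mean of centroids** (deterministic).
  $\sum_b w_{b,c}\,\text{centroid}(b)$. Summing over all member blocks is
  identical to summing over matching blocks only, since zero-weight blocks
  contribute nothing. The result lies in the convex hull of matching-block
  centroids, and two records collide only when their weight vectors are
  identical — S4 barely clusters artificially.

S3 and S4 coincide exactly when a single block matches. Both are
unimputable exactly when the unit total for the category is zero.

### Randomness and reproducibility

One master seed governs a batch. Each (record, strategy, replicate) triple
gets its own substream, seeded by a stable polynomial hash of the triple's
identifiers plus the master seed, so results are independent of record
order and of which other strategies run in the same call. Points inside
polygons are drawn by bounding-box rejection sampling (exact and cheap for
the rectangular blocks of the synthetic geographies; capped at 10,000
attempts per point for safety on thin polygons), making every run
bit-reproducible per seed.

## Geometry model

Coordinates must be planar meters in an equal-area projection (as with an
Albers-projected state block layer); the loader refuses anything not tagged
`crs_units = "m"` and the package does no geodesic math — error distances
are plain Euclidean. Blocks are simple polygons that tile their block group;
block groups nest in tracts, tracts in counties. Coarse units are
represented as the union of their member blocks, which makes three
operations exact without any polygon-union computation: uniform sampling
over a unit (pick a member block by area, then uniform inside), containment
(inside any member block), and unit area (sum of member areas). Validation
checks nesting consistency and pairwise non-overlap of sibling blocks
(exactly for axis-aligned rectangles, by interior-point sampling otherwise).

## The synthetic study conditions

Real registry + census data cannot be shipped, so the generator builds
census-like worlds in which every claim is testable. It emulates the
features that drive geoimputation accuracy, and nothing else:

* **Nested rectangular tessellation.** Block groups on a near-square grid,
  each subdivided into a grid of rectangular blocks; tracts and counties as
  super-grids. Rectangles keep containment and area arithmetic exact; the
  strategies never exploit shape, so realism in outlines adds nothing to the
  tests.
* **Density gradient.** Column widths and heights shrink geometrically along
  the x-axis so that block area falls by exactly `density_gradient` from
  first to last column, isotropically — dense areas have blocks that are
  smaller in both dimensions, as real urban blocks are. Expected population
  per block is flat, so an area gradient is a population-density gradient.
* **Demographic clustering.** Each race's population is allocated over
  blocks by one Dirichlet draw with a per-race concentration parameter: low
  concentration piles a race into few blocks (the minority-clustering regime
  where demographic weights are most informative), high concentration
  spreads it evenly. Within a race, people are distributed over sex × age
  cells by a smooth global profile, and one multinomial realisation
  conserves the total population exactly.
* **Records.** Sampled from the count table itself — (block, category) cell
  proportional to its count, true point uniform in the block — so every
  pristine record matches at least its own block and the deterministic
  strategies are always feasible. `make_unmatchable()` then switches the
  race of a seeded `ceiling(fraction * n)` subset to a race with zero count
  in their whole group, reproducing the real-data phenomenon of records that
  no strategy relying on demographics can place.

What the generator does **not** emulate: realistic polygon shapes, spatial
autocorrelation between neighbouring groups' demographics, household
structure, residency restrictions, or temporal address change (only its net
effect, the unmatchable records). Passing tests therefore demonstrate the
correctness of the machinery and the direction and mechanism of the
accuracy effects — not the absolute error magnitudes of any real region.

### Presets

Three shipped conditions (`scenario_preset()`):

| preset | groups × blocks | people / records | key knob |
|---|---|---|---|
| `uniform` | 25 × 16 | 50,000 / 2,000 | flat density, even races |
| `clustered_minorities` | 100 × 16 | 200,000 / 5,000 | minority concentrations 0.1–0.5 vs 10 for the majority |
| `density_gradient` | 100 × 16 | 100,000 / 4,000 | 10⁴-fold block-area gradient |

Sizes were chosen once as the smallest that give stable stratum means
(thousands of records, ≥ 25 records per density decade) while keeping a
full multi-replicate run in seconds on one CPU. On `clustered_minorities`
the mean error distance reproduces the canonical ordering S4 ≤ S3 ≤ S2 ≤ S1;
on `density_gradient` every strategy's mean error falls monotonically across
ascending density decades; and races generated with low concentration have
lower S4 error than evenly spread races — the three qualitative findings the
evaluation framework exists to measure. These are computed, not asserted:
see `tests/testthat/test-acceptance.R` and `scripts/acceptance.R`.

## Evaluation choices

* **Quartiles** use linear interpolation (R's default type 7); the rule is
  stated because quartile conventions differ across software.
* **Standard error** is `sd/sqrt(n)`; a stratum of one record reports `NA`,
  never zero.
* **Unimputable rows** are excluded from error summaries and reported
  separately by `imputable_fraction()` — accuracy is a property of the
  records a strategy could place.
* **Reporting age groups** default to five coarse bins (<20, 20–49, 50–64,
  65–84, 85+), configurable and deliberately independent of the schema's 23
  tabulation bins: the first stratifies results, the second defines
  categories.
* **Density bins** are right-open decades $[10^k, 10^{k+1})$ of block-group
  population per km², reflecting the orders-of-magnitude range of real
  densities.
* **Multiple imputation** averages each record's error over its replicates
  first, then summarises strata, so each record contributes one observation;
  it refuses S3/S4, whose replicates would be identical. The
  between-replicate spread is reported as the mean within-record standard
  deviation.
* **Sensitivity analysis** re-runs the identical pipeline (same master seed)
  with records coarsened to tracts and to counties; in single-run mode
  replicate 1 is scored.
* **Tract aggregation** reports each tract's *maximum* member error — a
  worst-case surface — and drops tracts with fewer than 0.001 imputed
  records per km², whose values would be unreliable.
* **IDW interpolation** uses power 2 and an all-samples neighbourhood
  (defaults chosen for determinism and simplicity; both are parameters), with
  an exact-hit rule: a cell within 1 nm of a sample takes that sample's
  value, keeping the surface bounded by the sample range.

## Degenerate inputs and numerical notes

Zero-area polygons are rejected at construction. Weight normalisation is
exact to 1e-12 (a single division by the group sum). The S3 tie-break and
the ascending-id ordering of `matching_blocks()` make all deterministic
paths bit-stable. Rejection sampling on rectangles accepts on the first
draw; on general polygons its cost is bbox area over polygon area per point.
Counts are stored as a dense integer matrix (blocks × 414); at the scale the
generator targets (thousands of blocks) this is a few MB and keeps every
weight lookup a vectorised slice.

## Limitations

* No significance testing between strategies is provided; summaries report
  means ± SE and leave inference to the user.
* The loader accepts GeoJSON only; shapefile support would need a spatial
  I/O dependency and real projects can convert with standard tools.
* Real-data error magnitudes (hundreds of meters in urban block groups, tens
  of kilometers in rural counties) depend on the actual geography; synthetic
  magnitudes scale with `base_block_size_m` and are meaningful only
  relatively.
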