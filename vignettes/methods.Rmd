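---
title: "Methods: mapping populations vulnerable to snakebite envenoming"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping populations vulnerable to snakebite envenoming}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snakevuln)
```

## The problem

Snakebite envenoming kills on the order of a hundred thousand people a
year, concentrated in poor rural communities, yet the geography of the
risk is poorly characterised. `snakevuln` implements a vulnerability
triangulation: where do medically important venomous snakes occur, and of
the people living there, who is also far from care, served by weak health
systems, and exposed to species for which no antivenom is marketed? The
unit of account is the population of a 5 × 5 km grid cell, aggregated to
second-level administrative divisions.

The pipeline has four stages, each usable on its own:

1. **Registry** — clean occurrence records, group species by data
   availability, join antivenom availability.
2. **Range refinement** — screen out-of-range records environmentally
   (MESS) and amend expert range maps where records are credible.
3. **Richness stacking** — rasterize ranges and count species per cell,
   stratified by WHO medical category and antivenom availability.
4. **Vulnerability** — intersect richness with travel-time remoteness and
   healthcare-quality deciles, and enumerate the affected population.

## Species registry and record hygiene

Occurrence records arrive as ad-hoc exports with duplicates and broken
coordinates. `dedup_occurrences()` removes rows missing either
coordinate, rows with out-of-range coordinates, and duplicates, where two
records of one species are duplicates when their (collection year,
latitude, longitude) tuples coincide. We deliberately read the duplicate
rule as the full tuple: deleting all records that merely share a
collection year *or* one coordinate would discard genuinely distinct
sites. Coordinates are compared after rounding to six decimal places
(about 10 cm, far below any plausible geopositioning precision);
missing-year records only collide with other missing-year records at the
same spot. The operation is idempotent, and record counts for grouping
are taken after deduplication.

Species fall into group A (no expert range map and no records — not
mappable, excluded), group B (a map but fewer than five records), or
group C (a map and at least five records). Five records is the smallest
training sample for which an environmental envelope is worth fitting; the
threshold lives in the configuration (`min_records_group_c`). Species
with records but no map cannot be placed on a map at all, so they are
excluded with group A and flagged loudly — the alternative (treating the
records as a range) would invent geography.

## Environmental screening (MESS)

Records falling outside a species' expert range may be range extensions
or misidentifications. We screen them with a multivariate environmental
similarity surface: for each covariate, the similarity of a candidate
value $v$ to the training sample (covariate values at within-range record
cells) is piecewise in $f$, the percentage of training values strictly
below $v$, with training extremes $m$ and $M$:

$$
s(v) = \begin{cases}
100\,(v - m)/(M - m) & f = 0 \\
2f & 0 < f \le 50 \\
2(100 - f) & 50 < f < 100 \\
100\,(M - v)/(M - m) & f = 100
\end{cases}
$$

The cell score is the minimum over covariates, so a cell is negative
exactly when at least one covariate lies outside its training envelope
(extrapolation). Ties at $v$ count as *not below*, matching the reference
formulation of the statistic. Two numerical conventions are ours and
documented here: degenerate training (all values equal) scores 100 at the
constant and −100 elsewhere, and the interpolation threshold is
$s \ge 0$ — the training extremes are attainable environments, so the
boundary counts as interpolation. Cells where any covariate is nodata
carry no classification, and records on such cells are excluded from
training with a tally. A fit is refused below two usable training
records (a one-point envelope is a point, not an interval); the species
then keeps its unamended expert range.

The surface is evaluated over the full covariate grid by default. A
windowed evaluation (`extent` argument) is available for large grids,
but a single unconditional extent keeps record classification, buffer
masking and the test oracles exactly comparable cell by cell, which we
value more than the saved arithmetic at the scales this package targets.

Covariate identities are configuration, not code: the default synthetic
stack carries eight bands, the number conventionally used for broad-scale
squamate distributions, but any named stack works.

## Range refinement

MESS-positive outside records are buffered with a disc of 0.898° radius
(about 100 km at the equator) — a generous allowance for species
movement and geopositioning error. Discs are planar circles in degree
space, approximated by 64-segment polygons (the radius is specified in
degrees, so planar discs are the faithful reading; at 64 segments the
area deficit is under 0.2%). Discs crossing the antimeridian are split
at ±180° and wrapped. The buffered area is masked by the interpolation
cells of the surface — "cells of environmental interpolation" is
cell-based language, so the mask is the union of interpolation cells as
grid squares — and merged with the expert range. Consequences we test
for: the contemporary range always contains the expert range; with no
MESS-positive outside records it equals it exactly; and buffered area
over nodata covariates (for example, sea) is masked out, which clips
ranges to covariate coverage without a separate coastline step.

Rasterization marks a cell present when its centre lies inside the
geometry; boundary points count as inside everywhere in the package, a
deterministic and inclusive convention. An approximate all-touched
variant (3 × 3 subsampling per cell) exists for users who prefer
over-coverage to under-coverage at coarse resolutions.

## Richness and strata

Per-species presence rasters are summed cell-wise into richness layers:
all included species, category one, category two, and the same three
restricted to species with no listed antivenom. Categories partition the
registry, so the category layers add exactly to the overall layer — an
invariant the tests assert, as is the cell-wise dominance of every
no-therapy layer by its unrestricted counterpart. Counts are small
integers (observed maxima in the teens), stored as plain integer
matrices.

## Health-system metrics

National units are ranked ascending by HAQ Index value and the unit at
rank $r$ of $N$ receives decile $\lfloor 10(r-1)/N \rfloor + 1$, so
decile 1 is the *lowest* healthcare access and quality, sizes differ by
at most one, and ties across a boundary are broken deterministically by
unit id. Subnational units never re-rank the thresholds; each is placed
in the decile whose national value interval $(\text{lower},
\text{upper}]$ contains its value, clamping at the extremes. The
half-open convention is our documented choice — some boundary rule is
needed and none is canonical.

Travel time to the nearest population centre of more than 50 000 people
proxies access to care. "More than 1 h / 3 h" is read strictly: a cell
at exactly 180 minutes is not remote. The cost of remoteness is made
concrete by `delay_mortality_scaling()`: 1.01 percentage points of
mortality per hour of delay between envenomation and antivenom
administration, a cohort-derived statistic extrapolated linearly — a
25 h journey implies a 25.25 point increase. The linearity far beyond
the source cohort's delays is an assumption, and the function attaches
it to its result as metadata rather than burying it.

## Vulnerability and enumeration

A cell is vulnerable when it is within the range of at least one species
of the chosen stratum, more than the travel threshold from a population
centre (default 3 h), and in a vulnerable HAQ decile (default 1–3). The
main report uses the no-therapy stratum; the all-species variant is
always computed alongside. Population is summed over masked cells,
assigned to admin-2 units by cell centre with a first-listed tie rule on
shared borders; cells outside every polygon are reported in an explicit
`unassigned` bucket, never dropped silently. Sums are kept as reals and
rounded half-up to whole persons only when reports are written.
`decile_table()` pivots country totals into a one-column-per-decile
matrix with a `Total` row; countries with no vulnerable population are
omitted from the matrix but retained (as zeros) in the full CSV.

Enumerated totals obey filter monotonicity — adding any conjunct never
increases a total — and aggregation conservation: admin-2 sums equal
country sums equal decile-column sums equal the grand total, exactly.
Both are asserted in the test suite.

## The synthetic world, and what it does not show

No public accession bundles all the inputs this analysis needs, so the
package ships a generator (`generate_scenario()`) that builds a complete
input tree with known ground truth. Its defaults are fixed once and
define the package's working conditions: a 60 × 60 grid at 0.5°, 12
mapped species (9 group C, 3 group B, plus one group-A registry row),
6 countries as vertical strips with 3 admin-2 bands each, 20 national
HAQ units (far more countries exist than carry the mapped species, and
decile construction needs at least ten nationals), subnational HAQ
values for one country, and 8 covariate bands built from affine
gradients plus a low-frequency sinusoid and small seeded noise. The
smooth fields make environments drift with distance, so near-range cells
interpolate and distant cells extrapolate — the qualitative structure
the screening step exploits. Sizes were chosen so the full pipeline,
oracle and suite run in well under a minute on one core.

Planted records carry their intended labels, enforced at generation time
by evaluating the similarity formula directly with a |score| margin of
10⁻⁶, so float-level agreement between generator and pipeline is
unambiguous. The brute-force oracle
(`expected_vulnerable_population()`) recomputes the entire report by
per-cell looping with its own naive primitives — scalar similarity,
convex-polygon disc tests, re-derived decile ranks — sharing no code
path with the pipeline modules.

What passing these tests shows: the implementation computes the stated
composition of operations exactly, at any seed. What it does not show:
that real snake ranges are rectangles (they are not), that real
covariates are smooth gradients, that expert maps are unbiased, or that
the proxies (travel time, HAQ deciles, market antivenom listings) track
true clinical outcomes. Those are properties of the data and the study
design, not of the code, and the package cannot test them.

## Formats and reproducibility

With no geospatial binary-format stack among the package's dependencies,
rasters are read and written as ESRI ASCII grids (a plain-text,
widely convertible format) and vector layers as GeoJSON; tables are CSV
and configuration is YAML. Every run writes a manifest with the config
snapshot, input checksums and package version; identical inputs and
configuration reproduce byte-identical reports, which the suite asserts.

```{r example, eval = FALSE}
dir <- tempfile("scenario")
simulate_scenario(scenario_spec(seed = 1), dir)
res <- run_pipeline(dir, output_dir = file.path(dir, "out"))
res$decile_table
autoplot(res$report)
```

## Known limitations

- Geometry is planar in degree space; discs and areas are not geodesic.
  The buffer radius is specified in degrees, so this is faithful to the
  method, but cell areas shrink with latitude and an equal-area mode is
  not provided.
- The linear delay-mortality statistic is extrapolated far beyond its
  source cohort.
- Admin assignment is by cell centre; units smaller than a cell can be
  missed.
- The all-touched rasterization variant is a subsampling approximation,
  not an exact polygon-cell intersection.
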