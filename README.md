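# snakevuln

Mapping populations vulnerable to snakebite envenoming.

Snakebite envenoming is a category A neglected tropical disease that
kills roughly a hundred thousand people a year, mostly in poor rural
communities of Africa and Asia. Who is most at risk is not just a matter
of where the snakes are: it is the intersection of snake presence with
weak health systems, long journeys to care, and the absence of a
marketed antivenom for the species at hand. `snakevuln` implements that
triangulation as a reusable, fully testable R pipeline:

- **Registry** — clean and deduplicate occurrence records, group species
  by data availability (A: unmappable; B: expert range map only; C: map
  plus ≥ 5 records), and join WHO-style antivenom availability.
- **Environmental screening** — fit per-species *multivariate
  environmental similarity surfaces* (MESS). With `f` the percentage of
  training values strictly below a candidate value `v`, and `m`/`M` the
  training extremes, the univariate score is

  ```
  s(v) = 100 (v − m)/(M − m)   if f = 0
         2 f                   if 0 < f ≤ 50
         2 (100 − f)           if 50 < f < 100
         100 (M − v)/(M − m)   if f = 100
  ```

  and a cell's score is the minimum over covariates — negative exactly
  when some covariate falls outside its training envelope. Out-of-range
  records on interpolation cells (score ≥ 0) are treated as valid.
- **Range refinement** — buffer valid records with 0.898° discs
  (≈ 100 km at the equator), mask by the interpolation cells, merge with
  the expert range; rasterize at a nominal 5 × 5 km.
- **Richness stacking** — per-cell species counts, stratified by WHO
  medical category (one/two) and antivenom availability.
- **Vulnerability** — a cell is vulnerable if it is within ≥ 1 species'
  range, more than 3 h travel from a ≥ 50 000-person centre, and in the
  lowest three deciles of the Healthcare Access and Quality (HAQ)
  Index; population is enumerated per cell and aggregated to admin-2
  units, countries, and deciles. A linear delay–mortality scaling
  (1.01 percentage points per hour of delay) expresses what remoteness
  costs.

Because no single public accession provides all inputs, the package
ships a first-class synthetic-data generator with planted ground truth
and an independent brute-force oracle, so every stage — and the whole
composition — is verified exactly.

## Worked example

```r
library(snakevuln)

dir <- tempfile("scenario")
simulate_scenario(scenario_spec(seed = 1), dir)   # write a synthetic world
res <- run_pipeline(dir, output_dir = file.path(dir, "out"))
```

The run logs each stage:

```
== stage: registry ==
dedup_occurrences: kept 98 of 106 (3 missing coordinate, 0 out of range, 5 duplicate)
registry: 13 species, 12 included (B=3, C=9)
== stage: ranges ==
ranges: 12 species rasterized, 7 amended beyond the expert range
== stage: vulnerability ==
vulnerability: 42328 in range, 11697 remote, 1424 vulnerable (all), 1374 (no therapy)
```

meaning: of 13 registry species one was unmappable and excluded; 7 of
the 9 group-C species had credible out-of-range records and their ranges
were amended; 42 328 synthetic persons live within ≥ 1 species' range,
11 697 of them more than 3 h from a population centre, and 1 374 are
additionally in HAQ deciles 1–3 *and* exposed to a species with no
therapy — the vulnerable population. The country-by-decile matrix
(`res$decile_table`) pivots those counts the way burden tables are
usually printed:

```
  country decile_1 decile_2 decile_3 ...
1 C1          1274        0        0
2 C2             0        0      100
3 Total       1274        0      100
```

`res$report` holds the admin-2 rows (one per unit, with vulnerable /
in-range / total population and the vulnerable share), `autoplot()`
methods draw the rasters and reports, and `tidy()`/`glance()` summarise
fitted MESS objects. Outputs on disk include richness and mask rasters
(ESRI ASCII grid), the admin-2 and country-by-decile CSVs,
`summary.json`, and a manifest with input checksums — reruns on the same
inputs are byte-identical.

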